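#' DiscretizedImage: fixed-bin-size discretized intensity image
#'
#' @slot bins integer matrix of 1-based bin indices; unmasked pixels NA.
#' @slot mask logical matrix.
#' @slot nBins number of bins.
#' @slot binWidth width used.
#' @slot origin masked intensity minimum used as the binning origin.
#' @export
setClass("DiscretizedImage", representation(
  bins = "matrix", mask = "matrix", nBins = "integer",
  binWidth = "numeric", origin = "numeric"))

setMethod("show", "DiscretizedImage", function(object) {
  cat(sprintf("DiscretizedImage %dx%d: %d bins, width %g, origin %g\n",
              nrow(object@bins), ncol(object@bins), object@nBins,
              object@binWidth, object@origin))
})

#' Fixed-bin-size intensity discretization
#'
#' Bins masked pixels as floor((I - min_masked)/bin_width) + 1 with the
#' per-image masked minimum as origin (shift-invariant) and a cohort-global
#' width. The number of bins is ceiling(range/bin_width) (minimum 1); the
#' top edge is clamped into the last bin.
#'
#' @param image 2D numeric matrix.
#' @param mask logical matrix, same shape, at least one TRUE pixel.
#' @param bin_width positive bin width.
#' @return a [DiscretizedImage-class].
#' @export
#' @examples
#' img <- matrix(c(0, 0.5, 1.0, 2.6), 2, 2)
#' d <- discretizeImage(img, matrix(TRUE, 2, 2), 1)
#' d@bins  # bins 1,1,2,3
discretizeImage <- function(image, mask, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!any(mask)) stop("empty mask")
  v <- image[mask]
  origin <- min(v)
  rng <- max(v) - origin
  nb <- max(1L, as.integer(ceiling(rng / bin_width - 1e-12)))
  b <- pmin(as.integer(floor((v - origin) / bin_width)) + 1L, nb)
  bins <- matrix(NA_integer_, nrow(image), ncol(image))
  bins[mask] <- b
  new("DiscretizedImage", bins = bins, mask = mask, nBins = nb,
      binWidth = bin_width, origin = origin)
}

#' Number of bins an image yields at a candidate width
#'
#' @param image,mask as in [discretizeImage()].
#' @param bin_width candidate width.
#' @return integer bin count.
#' @export
nBinsAtWidth <- function(image, mask, bin_width) {
  v <- image[mask]
  max(1L, as.integer(ceiling((max(v) - min(v)) / bin_width - 1e-12)))
}

#' Cohort-global bin-width selection
#'
#' Returns the largest candidate width at which no masked image in the
#' cohort becomes completely homogeneous (a single bin); errors (naming
#' the offending image) if no candidate qualifies.
#'
#' @param images list of 2D matrices (one modality across the cohort).
#' @param masks list of logical matrices, parallel to `images`.
#' @param candidate_widths positive finite candidate widths.
#' @return the selected bin width.
#' @export
selectBinWidth <- function(images, masks, candidate_widths) {
  if (any(candidate_widths <= 0) || any(!is.finite(candidate_widths)))
    stop("candidate widths must be positive and finite")
  nm <- names(images)
  if (is.null(nm)) nm <- as.character(seq_along(images))
  ranges <- vapply(seq_along(images), function(i) {
    v <- images[[i]][masks[[i]]]
    max(v) - min(v)
  }, numeric(1))
  ok <- vapply(candidate_widths, function(w) all(ranges > w + 1e-12),
               logical(1))
  if (!any(ok)) {
    worst <- nm[which.min(ranges)]
    stop(sprintf(
      "no candidate width keeps all images multi-bin (image '%s' has masked range %.4g)",
      worst, min(ranges)))
  }
  max(candidate_widths[ok])
}

## GLCM neighbour offsets: the 4 unique directions at distance 1
## (0, 45, 90, 135 degrees) in (row, col) steps.
.glcmOffsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

#' Gray level co-occurrence matrix
#'
#' Counts ordered pairs of masked 8-neighbours at distance 1 over the four
#' unique 2D directions, pooled across directions, symmetrized and
#' normalized to sum 1. Pairs with either pixel outside the mask are
#' excluded.
#'
#' @param disc a [DiscretizedImage-class].
#' @return nBins x nBins matrix summing to 1, or a matrix of NA if the
#'   mask admits no valid neighbour pair (flagged with a warning).
#' @export
#' @examples
#' d <- discretizeImage(matrix(c(1, 1, 2, 2), 2, 2), matrix(TRUE, 2, 2), 1)
#' glcmMatrix(d)
glcmMatrix <- function(disc) {
  bins <- disc@bins
  nb <- disc@nBins
  nr <- nrow(bins); nc <- ncol(bins)
  counts <- matrix(0, nb, nb)
  for (off in .glcmOffsets()) {
    di <- off[1]; dj <- off[2]
    ri <- seq_len(nr - di)
    cj <- max(1L, 1L - dj):min(nc, nc - dj)
    a <- bins[ri, cj, drop = FALSE]
    b <- bins[ri + di, cj + dj, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    idx <- (a[keep] - 1L) * nb + b[keep]
    counts <- counts + matrix(tabulate(idx, nbins = nb * nb), nb, nb)
  }
  counts <- counts + t(counts)   # symmetrize (count both pair orders)
  if (sum(counts) == 0) {
    warning("no valid neighbour pairs in mask; GLCM undefined")
    return(matrix(NA_real_, nb, nb))
  }
  counts / sum(counts)
}

#' GLCM feature catalog
#'
#' Standard co-occurrence features computed from a normalized, symmetric
#' GLCM; entropies use log base 2 (bits).
#'
#' @param P normalized GLCM from [glcmMatrix()].
#' @return named numeric vector of features.
#' @export
#' @examples
#' glcmFeatures(matrix(1))["joint_entropy"]  # single bin: 0 bits
glcmFeatures <- function(P) {
  if (any(is.na(P)))
    return(stats::setNames(rep(NA_real_, length(.glcmFeatureNames())),
                           .glcmFeatureNames()))
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)                     # symmetric: px == py
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  pos <- P > 0
  ent <- -sum(P[pos] * log2(P[pos]))
  ## diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  dpos <- p_diff > 0; spos <- p_sum > 0
  da <- sum(k_diff * p_diff)
  c(autocorrelation = sum(i * j * P),
    joint_average = mu,
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 1,
    difference_average = da,
    difference_entropy = -sum(p_diff[dpos] * log2(p_diff[dpos])),
    difference_variance = sum((k_diff - da)^2 * p_diff),
    joint_energy = sum(P^2),
    joint_entropy = ent,
    sum_average = sum(k_sum * p_sum),
    sum_entropy = -sum(p_sum[spos] * log2(p_sum[spos])),
    sum_squares = sig2,
    id = sum(P / (1 + abs(i - j))),
    idn = sum(P / (1 + abs(i - j) / ng)),
    idm = sum(P / (1 + (i - j)^2)),
    idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum(P[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(P))
}

.glcmFeatureNames <- function() names(glcmFeatures(matrix(1)))

#' Gray level size zone matrix
#'
#' Zones are 8-connected components of equal-bin masked pixels; entry
#' (g, s) counts the zones of gray level g and size s.
#'
#' @param disc a [DiscretizedImage-class].
#' @return nBins x maxZoneSize matrix of zone counts.
#' @export
#' @examples
#' d <- discretizeImage(matrix(1, 3, 3), matrix(TRUE, 3, 3), 1)
#' glszmMatrix(d)  # single 9-pixel zone
glszmMatrix <- function(disc) {
  bins <- disc@bins
  nb <- disc@nBins
  nr <- nrow(bins); nc <- ncol(bins)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  for (off in .glcmOffsets()) {
    di <- off[1]; dj <- off[2]
    ri <- seq_len(nr - di)
    cj <- max(1L, 1L - dj):min(nc, nc - dj)
    a <- bins[ri, cj, drop = FALSE]
    b <- bins[ri + di, cj + dj, drop = FALSE]
    keep <- !is.na(a) & !is.na(b) & a == b
    if (!any(keep)) next
    ia <- id[ri, cj, drop = FALSE][keep]
    ib <- id[ri + di, cj + dj, drop = FALSE][keep]
    edges[[length(edges) + 1L]] <- rbind(ia, ib)
  }
  maskedIds <- id[disc@mask]
  g <- igraph::make_graph(edges = if (length(edges))
    as.vector(do.call(cbind, edges)) else integer(0),
    n = nr * nc, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[maskedIds]
  zoneSize <- table(memb)
  zoneLevel <- bins[disc@mask][!duplicated(memb)]
  names(zoneLevel) <- memb[!duplicated(memb)]
  zoneLevel <- zoneLevel[names(zoneSize)]
  smax <- max(zoneSize)
  Z <- matrix(0, nb, smax)
  for (k in seq_along(zoneSize))
    Z[zoneLevel[k], zoneSize[k]] <- Z[zoneLevel[k], zoneSize[k]] + 1
  Z
}

#' GLSZM feature catalog
#'
#' Size-zone features including the two long-range organization measures:
#' zone-size non-uniformity (sum over sizes of squared zone counts over the
#' total zone count) and gray-level non-uniformity (the analogue over gray
#' levels), plus the standard emphasis/variance/entropy companions.
#'
#' @param Z zone matrix from [glszmMatrix()].
#' @param n_masked number of masked pixels (for zone percentage).
#' @return named numeric vector of features.
#' @export
#' @examples
#' Z <- matrix(0, 2, 3); Z[1, 3] <- 1; Z[2, 3] <- 1
#' glszmFeatures(Z, 6)[c("zone_size_nonuniformity",
#'                       "gray_level_nonuniformity")]  # 2, 1
glszmFeatures <- function(Z, n_masked) {
  Nz <- sum(Z)
  if (Nz < 1) stop("zone matrix has zero zones")
  ng <- nrow(Z); smax <- ncol(Z)
  gl <- seq_len(ng); sz <- seq_len(smax)
  pg <- rowSums(Z); ps <- colSums(Z)
  p <- Z / Nz
  muG <- sum(gl * rowSums(p))
  muS <- sum(sz * colSums(p))
  ppos <- p[p > 0]
  c(small_area_emphasis = sum(t(t(Z) / sz^2)) / Nz,
    large_area_emphasis = sum(t(t(Z) * sz^2)) / Nz,
    gray_level_nonuniformity = sum(pg^2) / Nz,
    gray_level_nonuniformity_norm = sum(pg^2) / Nz^2,
    zone_size_nonuniformity = sum(ps^2) / Nz,
    zone_size_nonuniformity_norm = sum(ps^2) / Nz^2,
    zone_percentage = Nz / n_masked,
    gray_level_variance = sum((gl - muG)^2 * rowSums(p)),
    zone_size_variance = sum((sz - muS)^2 * colSums(p)),
    zone_entropy = -sum(ppos * log2(ppos)),
    low_gray_emphasis = sum(Z / gl^2) / Nz,
    high_gray_emphasis = sum(Z * gl^2) / Nz,
    small_area_low_gray = sum(outer(1 / gl^2, 1 / sz^2) * Z) / Nz,
    small_area_high_gray = sum(outer(gl^2, 1 / sz^2) * Z) / Nz,
    large_area_low_gray = sum(outer(1 / gl^2, sz^2) * Z) / Nz,
    large_area_high_gray = sum(outer(gl^2, sz^2) * Z) / Nz)
}

#' First-order intensity feature catalog
#'
#' Statistics of the masked intensities plus histogram entropy/uniformity
#' on the discretized bins (log base 2).
#'
#' @param image 2D numeric matrix.
#' @param mask logical matrix.
#' @param disc the matching [DiscretizedImage-class] (for the histogram
#'   features).
#' @return named numeric vector of features.
#' @export
firstOrderFeatures <- function(image, mask, disc) {
  v <- image[mask]
  n <- length(v)
  m <- mean(v)
  va <- mean((v - m)^2)
  s <- sqrt(va)
  q <- unname(quantile(v, c(0.1, 0.5, 0.9, 0.25, 0.75)))
  h <- tabulate(disc@bins[mask], nbins = disc@nBins) / n
  hpos <- h[h > 0]
  c(mean = m,
    variance = va,
    sd = s,
    skewness = if (s > 0) mean((v - m)^3) / s^3 else 0,
    kurtosis = if (s > 0) mean((v - m)^4) / s^4 else 0,
    energy = sum(v^2),
    rms = sqrt(mean(v^2)),
    min = min(v), p10 = q[1], median = q[2], p90 = q[3], max = max(v),
    range = max(v) - min(v),
    iqr = q[5] - q[4],
    mean_abs_dev = mean(abs(v - m)),
    entropy = -sum(hpos * log2(hpos)),
    uniformity = sum(hpos^2))
}
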