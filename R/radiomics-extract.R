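## Two-threshold (three-class) Otsu on a 256-bin histogram; returns the
## two cuts maximizing the between-class variance. The lowest cut
## separates void background from tissue even when bright sub-structures
## (cell nests) make the histogram trimodal.
.otsu2 <- function(v, nbins = 256L) {
  h <- tabulate(pmin(as.integer(v * (nbins - 1L)) + 1L, nbins), nbins)
  w <- cumsum(h)
  m <- cumsum(h * seq_len(nbins))
  wT <- w[nbins]; mT <- m[nbins]
  best <- -Inf; t1b <- 1L; t2b <- 2L
  for (t1 in 1:(nbins - 2L)) {
    w1 <- w[t1]
    if (w1 == 0) next
    t2 <- (t1 + 1L):(nbins - 1L)
    w2 <- w[t2] - w[t1]
    w3 <- wT - w[t2]
    s <- m[t1]^2 / w1 +
      ifelse(w2 > 0, (m[t2] - m[t1])^2 / w2, 0) +
      ifelse(w3 > 0, (mT - m[t2])^2 / w3, 0)
    s[w2 == 0 | w3 == 0] <- -Inf
    k <- which.max(s)
    if (s[k] > best) { best <- s[k]; t1b <- t1; t2b <- t2[k] }
  }
  c(t1b, t2b) / (nbins - 1L)
}

#' Automatic region-of-interest mask
#'
#' Log-compresses the intensities (so bright sub-structures such as cell
#' nests cannot dominate the histogram), median-smooths, separates the
#' void background with a two-threshold Otsu rule (taking the lowest of
#' the two optimal cuts, robust to trimodal dark/tissue/bright
#' histograms), keeps the largest connected foreground component and
#' fills its holes. A constant image, or a threshold that empties the
#' foreground, falls back to an all-true mask with a warning.
#'
#' @param image 2D nonnegative numeric matrix.
#' @return logical matrix of the same shape, never empty.
#' @export
#' @examples
#' img <- matrix(0, 48, 48)
#' img[16:32, 16:32] <- 1
#' mean(makeMask(img)[16:32, 16:32])
makeMask <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: falling back to an all-true mask")
    return(matrix(TRUE, nrow(image), ncol(image)))
  }
  shifted <- image - rng[1]
  scale <- stats::median(shifted[shifted > 0])
  lg <- log1p(shifted / max(scale, .Machine$double.eps))
  norm <- lg / max(lg)
  sm <- EBImage::medianFilter(EBImage::Image(norm), size = 1)
  th <- .otsu2(as.numeric(EBImage::imageData(sm)))[1]
  bw <- EBImage::imageData(sm) > th
  if (!any(bw)) {
    warning("threshold emptied the image: falling back to an all-true mask")
    return(matrix(TRUE, nrow(image), ncol(image)))
  }
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(keep * 1)) > 0
  matrix(as.logical(filled), nrow(image), ncol(image))
}

#' Radiomic feature catalog of one multimodal plane
#'
#' Computes the full feature catalog (first-order + GLCM + GLSZM) for each
#' of the four modality images under that modality's mask, at the
#' cohort-global bin widths. Feature names follow
#' `modality.family.feature` (e.g. `OCT.glcm.joint_entropy`). Features that
#' are undefined for a plane (e.g. a mask without neighbour pairs) are
#' returned as NA and reported.
#'
#' @param plane a [MultimodalPlane-class].
#' @param bin_widths named numeric with entries OCT, TPEF, SHG, MPM.
#' @param masks optional named list of per-modality masks; by default they
#'   are derived per modality with [makeMask()].
#' @return named numeric feature row (length constant across planes).
#' @export
extractFeatures <- function(plane, bin_widths, masks = NULL) {
  if (!all(planeModalities() %in% names(bin_widths)))
    stop("bin_widths must name all 4 modalities")
  out <- numeric(0)
  for (mod in planeModalities()) {
    img <- plane@images[[mod]]
    msk <- if (is.null(masks)) makeMask(img) else masks[[mod]]
    disc <- discretizeImage(img, msk, bin_widths[[mod]])
    fo <- firstOrderFeatures(img, msk, disc)
    gl <- glcmFeatures(glcmMatrix(disc))
    zn <- glszmFeatures(glszmMatrix(disc), sum(msk))
    row <- c(stats::setNames(fo, paste0(mod, ".firstorder.", names(fo))),
             stats::setNames(gl, paste0(mod, ".glcm.", names(gl))),
             stats::setNames(zn, paste0(mod, ".glszm.", names(zn))))
    out <- c(out, row)
  }
  if (anyNA(out))
    message("extractFeatures: undefined features on plane ", plane@planeId,
            ": ", paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Radiomic feature table of a cohort
#'
#' Generates per-modality masks, selects the cohort-global bin width per
#' modality (largest candidate width leaving every masked image with at
#' least two bins), and extracts the full catalog for every plane.
#'
#' @param cohort a [PituitaryCohort-class].
#' @param bin_widths "auto" for the cohort-global rule, or a named numeric
#'   with entries OCT, TPEF, SHG, MPM pinning the widths.
#' @param candidate_widths candidate widths for the auto rule.
#' @param mask_mode "auto" derives per-modality masks with [makeMask()];
#'   "plane" uses each plane's stored generator mask for all modalities.
#' @return data.frame with `plane_id`, `biopsy_id`, `class_name`, `label`
#'   then one column per feature; attribute `bin_widths` records the
#'   widths used.
#' @export
extractFeatureTable <- function(cohort, bin_widths = "auto",
                                candidate_widths = seq(0.02, 5, by = 0.02),
                                mask_mode = c("auto", "plane")) {
  mask_mode <- match.arg(mask_mode)
  pls <- planes(cohort)
  masks <- lapply(pls, function(p) {
    if (mask_mode == "plane")
      stats::setNames(rep(list(p@mask), 4), planeModalities())
    else
      stats::setNames(lapply(planeModalities(),
                             function(m) makeMask(p@images[[m]])),
                      planeModalities())
  })
  if (identical(bin_widths, "auto")) {
    bin_widths <- vapply(planeModalities(), function(mod) {
      selectBinWidth(lapply(pls, function(p) p@images[[mod]]),
                     lapply(seq_along(pls),
                            function(i) masks[[i]][[mod]]),
                     candidate_widths)
    }, numeric(1))
  }
  rows <- lapply(seq_along(pls), function(i)
    extractFeatures(pls[[i]], bin_widths, masks = masks[[i]]))
  feat <- do.call(rbind, rows)
  meta <- data.frame(
    plane_id = vapply(pls, function(p) p@planeId, character(1)),
    biopsy_id = vapply(pls, function(p) p@biopsyId, character(1)),
    class_name = vapply(pls, className, character(1)),
    label = vapply(pls, binaryLabel, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(meta, as.data.frame(feat, row.names = NULL))
  attr(out, "bin_widths") <- bin_widths
  out
}

#' Pearson-correlation redundancy reduction
#'
#' Greedy elimination of redundant features: constant columns are dropped
#' first; then, repeatedly, the feature pair with the largest |Pearson r|
#' at or above the threshold is visited (ties broken by column order) and
#' the member with the larger mean |r| to all remaining features is
#' dropped (ties: the later column). Terminates when no surviving pair
#' reaches the threshold.
#'
#' @param table data.frame or matrix whose numeric columns are features;
#'   non-numeric columns (metadata) are carried through untouched.
#' @param threshold absolute Pearson correlation threshold (default 0.85).
#' @return the table restricted to surviving features; attribute `dropped`
#'   lists the removed feature names.
#' @export
#' @examples
#' x <- data.frame(a = 1:10, b = (1:10) * 2, c = rnorm(10))
#' colnames(reduceRedundancy(x, 0.85))
reduceRedundancy <- function(table, threshold = 0.85) {
  df <- as.data.frame(table)
  isFeat <- vapply(df, is.numeric, logical(1))
  X <- as.matrix(df[, isFeat, drop = FALSE])
  if (ncol(X) < 2) stop("need >= 2 features")
  if (nrow(X) < 3) stop("need >= 3 samples")
  dropped <- character(0)
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || anyNA(v))
  if (any(const)) {
    dropped <- colnames(X)[const]
    message("reduceRedundancy: dropping constant/NA features: ",
            paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  repeat {
    C <- abs(stats::cor(X))
    diag(C) <- 0
    if (max(C) < threshold) break
    hit <- which(C == max(C), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    meanAbs <- rowMeans(C)
    pair <- sort(hit)
    victim <- if (meanAbs[pair[2]] >= meanAbs[pair[1]]) pair[2] else pair[1]
    dropped <- c(dropped, colnames(X)[victim])
    X <- X[, -victim, drop = FALSE]
    if (ncol(X) < 2) break
  }
  keep <- c(colnames(df)[!isFeat], colnames(X))
  out <- df[, keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
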