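# Independent brute-force oracles used to validate the vectorized texture
# implementations and classifier metrics.

# Ordered-pair co-occurrence counts by explicit loops over all pixels and
# all 8 neighbour offsets (equivalent to the 4 unique directions counted
# in both orders), masked pairs only; normalized to sum 1.
oracleGLCM <- function(bins, mask) {
  nb <- max(bins[mask])
  nr <- nrow(bins); nc <- ncol(bins)
  counts <- matrix(0, nb, nb)
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (!mask[ii, jj]) next
      counts[bins[i, j], bins[ii, jj]] <-
        counts[bins[i, j], bins[ii, jj]] + 1
    }
  }
  if (sum(counts) == 0) return(matrix(NA_real_, nb, nb))
  counts / sum(counts)
}

# 8-connected equal-level zones by an explicit stack-based flood fill;
# returns the zone matrix (gray level x zone size counts).
oracleGLSZM <- function(bins, mask) {
  nb <- max(bins[mask])
  nr <- nrow(bins); nc <- ncol(bins)
  visited <- !mask
  zones <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (visited[i, j]) next
    lev <- bins[i, j]
    stack <- list(c(i, j))
    visited[i, j] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (visited[ii, jj] || bins[ii, jj] != lev) next
        visited[ii, jj] <- TRUE
        stack[[length(stack) + 1L]] <- c(ii, jj)
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  zm <- do.call(rbind, zones)
  Z <- matrix(0, nb, max(zm[, 2]))
  for (k in seq_len(nrow(zm)))
    Z[zm[k, 1], zm[k, 2]] <- Z[zm[k, 1], zm[k, 2]] + 1
  Z
}

# Connected bright components of a thresholded image (flood fill), for
# validating nest counts on generated gland planes.
countBrightComponents <- function(image, threshold) {
  bw <- image > threshold
  mode(bw) <- "integer"
  oracleGLSZM(bw + 1L, matrix(TRUE, nrow(bw), ncol(bw))) -> Z
  if (nrow(Z) < 2) 0L else sum(Z[2, ])
}

# Mean silhouette width on the first `d` score columns against labels,
# computed directly from pairwise distances.
meanSilhouette <- function(scores, labels, d = ncol(scores)) {
  X <- scores[, seq_len(d), drop = FALSE]
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(tapply(D[i, !own], labels[!own], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Tiny feature table with one informative feature and noise features, for
# exercising the MC CV machinery quickly.
makeToyFeatureTable <- function(n_per_sub = 8, n_noise = 6, seed = 1,
                                signal = 6) {
  set.seed(seed)
  subs <- c("gland", "lactotroph", "null_cell", "gonadotroph",
            "somatotroph_mammosomatotroph", "corticotroph")
  cls <- rep(subs, each = n_per_sub)
  lab <- ifelse(cls == "gland", "gland", "adenoma")
  n <- length(cls)
  X <- matrix(rnorm(n * n_noise), n,
              dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  inf <- ifelse(lab == "adenoma", signal, 0) + rnorm(n)
  data.frame(plane_id = sprintf("p%03d", seq_len(n)),
             biopsy_id = paste0(cls, "_b", rep(1:2, length.out = n)),
             class_name = cls, label = lab, informative = inf, X,
             stringsAsFactors = FALSE)
}
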