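#' @import methods
#' @importFrom stats rnorm runif rpois rgamma var sd cor quantile median
#'   prcomp shapiro.test t.test aov pf predict setNames dist
#' @importFrom utils head read.csv write.csv
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic child seed from a parent seed and a salt; stays within
## 32-bit integer range.
deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 7919) %%
               2147483647)
}

## Separable Gaussian blur with edge replication (kernel radius 3*sigma).
gaussianBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, n) c(rep(x[1], n), x, rep(x[length(x)], n))
  conv1 <- function(x) {
    y <- stats::filter(pad(x, r), k, sides = 2)
    as.numeric(y[(r + 1):(length(x) + r)])
  }
  m <- apply(mat, 2, conv1)
  t(apply(t(m), 2, conv1))
}

## Add `value` inside discs of radius r at integer-ish centers (cx, cy).
## Vectors cx, cy, r, value are recycled to a common length.
stampDiscs <- function(mat, cx, cy, r, value) {
  n <- max(length(cx), length(cy), length(r), length(value))
  cx <- rep_len(cx, n); cy <- rep_len(cy, n)
  r <- rep_len(r, n); value <- rep_len(value, n)
  nr <- nrow(mat); nc <- ncol(mat)
  for (i in seq_len(n)) {
    i0 <- max(1L, floor(cy[i] - r[i])); i1 <- min(nr, ceiling(cy[i] + r[i]))
    j0 <- max(1L, floor(cx[i] - r[i])); j1 <- min(nc, ceiling(cx[i] + r[i]))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - cy[i])^2, (jj - cx[i])^2, `+`)
    sel <- d2 <= r[i]^2
    mat[ii, jj][sel] <- mat[ii, jj][sel] + value[i]
  }
  mat
}

## Add an anisotropic Gaussian ridge (elongated structure) centered at
## (cx, cy), orientation theta, axial sigmas (sl, sw), peak `value`.
stampRidge <- function(mat, cx, cy, theta, sl, sw, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  ext <- 3 * max(sl, sw)
  i0 <- max(1L, floor(cy - ext)); i1 <- min(nr, ceiling(cy + ext))
  j0 <- max(1L, floor(cx - ext)); j1 <- min(nc, ceiling(cx + ext))
  if (i0 > i1 || j0 > j1) return(mat)
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  mat[ii, jj] <- mat[ii, jj] + value * exp(-(u^2 / (2 * sl^2) +
                                               v^2 / (2 * sw^2)))
  mat
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
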