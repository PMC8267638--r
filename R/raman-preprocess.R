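#' Raman preprocessing configuration
#'
#' Parameters of the spectral preprocessing protocol: iterative-polynomial
#' fluorescence-background removal, Savitzky-Golay smoothing and 0-1
#' normalization anchored to the C-H stretch band.
#'
#' @param poly_order polynomial order of the baseline fit (>= 1).
#' @param max_iterations iteration cap for the peak-stripping loop.
#' @param convergence_tol relative-change threshold for convergence.
#' @param sg_window odd Savitzky-Golay window length (>= sg_order + 2).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param ch_band_center C-H anchor band center in cm^-1.
#' @param band_halfwidth half-width (cm^-1) of band-intensity windows.
#' @return a named list of class `preprocessConfig`.
#' @export
#' @examples
#' preprocessConfig(sg_window = 11)
preprocessConfig <- function(poly_order = 5, max_iterations = 100,
                             convergence_tol = 1e-6, sg_window = 9,
                             sg_order = 3, ch_band_center = 2945,
                             band_halfwidth = 5) {
  if (sg_window %% 2 == 0) stop("sg_window must be odd")
  if (sg_window < sg_order + 2) stop("sg_window must be >= sg_order + 2")
  if (poly_order < 1) stop("poly_order must be >= 1")
  structure(list(poly_order = poly_order, max_iterations = max_iterations,
                 convergence_tol = convergence_tol, sg_window = sg_window,
                 sg_order = sg_order, ch_band_center = ch_band_center,
                 band_halfwidth = band_halfwidth),
            class = "preprocessConfig")
}

## Iterative polynomial (modified polyfit) baseline estimation for a
## spectra matrix Y (rows = spectra). Fit a degree-d polynomial, clip the
## working spectrum to min(spectrum, fit), refit, until the maximum
## relative change of the working spectrum drops below tol.
.baselineFitMatrix <- function(Y, axis, config) {
  d <- config$poly_order
  t <- (axis - mean(axis)) / (diff(range(axis)) / 2)
  X <- outer(t, 0:d, `^`)
  qrX <- qr(X)
  Q <- qr.Q(qrX)                      # orthonormal basis of the fit space
  W <- Y
  scale <- pmax(apply(Y, 1, function(r) diff(range(r))), .Machine$double.eps)
  active <- rep(TRUE, nrow(Y))
  fit <- W
  for (it in seq_len(config$max_iterations)) {
    fit[active, ] <- tcrossprod(W[active, , drop = FALSE] %*% Q, Q)
    Wnew <- pmin(W, fit)
    delta <- apply(abs(Wnew - W), 1, max) / scale
    W <- Wnew
    active <- delta >= config$convergence_tol
    if (!any(active)) break
  }
  fit
}

#' Remove the fluorescence background from a spectrum
#'
#' Implements the iterative-polynomial (peak-stripping) baseline algorithm:
#' a polynomial of order `poly_order` is fitted to the spectrum, the
#' working spectrum is replaced by the pointwise minimum of itself and the
#' fit, and the fit is repeated until the maximum relative change falls
#' below `convergence_tol` (or `max_iterations` is reached). The converged
#' fit is the baseline estimate; corrected values may be slightly negative
#' at the noise scale.
#'
#' @param spectrum numeric vector of raw intensities.
#' @param axis strictly increasing wavenumber axis, same length.
#' @param config a [preprocessConfig()].
#' @return list with elements `corrected` and `baseline`.
#' @export
#' @examples
#' ax <- seq(600, 3100, by = 5)
#' y <- 2 + 0.001 * (ax - 1800)^2 / 1000
#' out <- removeBaseline(y, ax)
#' max(abs(out$corrected))  # pure polynomial: ~0
removeBaseline <- function(spectrum, axis, config = preprocessConfig()) {
  if (length(spectrum) != length(axis))
    stop("spectrum and axis must have the same length")
  if (length(spectrum) < config$poly_order + 2)
    stop("spectrum too short for the requested polynomial order")
  if (any(!is.finite(spectrum))) stop("non-finite values in spectrum")
  if (is.unsorted(axis, strictly = TRUE))
    stop("axis must be strictly increasing")
  base <- drop(.baselineFitMatrix(matrix(spectrum, 1), axis, config))
  list(corrected = spectrum - base, baseline = base)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing with the configured window and
#' order; endpoints are handled by the filter's polynomial edge fits, so a
#' polynomial of degree <= `sg_order` passes through unchanged.
#'
#' @inheritParams removeBaseline
#' @return smoothed numeric vector.
#' @export
smoothSpectrum <- function(spectrum, config = preprocessConfig()) {
  if (length(spectrum) < config$sg_window)
    stop("sg_window larger than the spectrum")
  signal::sgolayfilt(spectrum, p = config$sg_order, n = config$sg_window)
}

#' 0-1 normalization to the C-H band
#'
#' Subtracts the spectrum minimum and divides by the (minimum-subtracted)
#' mean intensity within +/- `band_halfwidth` of the C-H anchor band
#' (default 2945 cm^-1), so the output minimum is 0 and the C-H window mean
#' is 1. Scale- and shift-invariant by construction.
#'
#' @inheritParams removeBaseline
#' @return normalized numeric vector.
#' @export
normalizeCH <- function(spectrum, axis, config = preprocessConfig()) {
  win <- abs(axis - config$ch_band_center) <= config$band_halfwidth
  if (!any(win)) stop("C-H band center outside the wavenumber axis")
  iCH <- mean(spectrum[win])
  lo <- min(spectrum)
  if (iCH - lo <= .Machine$double.eps * max(1, abs(iCH)))
    stop("degenerate spectrum: C-H band intensity equals the minimum")
  (spectrum - lo) / (iCH - lo)
}

#' Preprocess a full Raman map
#'
#' Applies, per spectrum and in this order: baseline removal -> smoothing
#' -> C-H normalization. Degenerate spectra (C-H intensity at the spectrum
#' minimum, e.g. all-zero rows) are excluded rather than aborting the map;
#' their original position indices are recorded in the `excluded` attribute
#' of the returned map and reported via a message.
#'
#' @param map a [RamanMap-class].
#' @param config a [preprocessConfig()].
#' @return a [RamanMap-class] of preprocessed spectra (row order preserved,
#'   excluded rows dropped), with attribute `excluded` holding the dropped
#'   position indices.
#' @export
#' @examples
#' sp <- tissueClassSpec("gland", noise_sd = 0)
#' m <- generateRamanMap(sp, n_positions = 3, seed = 1)
#' pm <- preprocessMap(m)
preprocessMap <- function(map, config = preprocessConfig()) {
  Y <- map@spectra
  axis <- map@wavenumbers
  base <- .baselineFitMatrix(Y, axis, config)
  corr <- Y - base
  sm <- t(apply(corr, 1, function(r)
    signal::sgolayfilt(r, p = config$sg_order, n = config$sg_window)))
  win <- abs(axis - config$ch_band_center) <= config$band_halfwidth
  iCH <- rowMeans(sm[, win, drop = FALSE])
  lo <- apply(sm, 1, min)
  ok <- (iCH - lo) > 1e-12 * pmax(1, abs(iCH))
  if (any(!ok))
    message(sprintf("preprocessMap: excluded %d degenerate spectra (positions %s)",
                    sum(!ok),
                    paste(map@positions[!ok], collapse = ", ")))
  norm <- (sm[ok, , drop = FALSE] - lo[ok]) / (iCH[ok] - lo[ok])
  out <- new("RamanMap", mapId = map@mapId, className = map@className,
             wavenumbers = axis, spectra = norm,
             positions = map@positions[ok])
  attr(out, "excluded") <- map@positions[!ok]
  out
}
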