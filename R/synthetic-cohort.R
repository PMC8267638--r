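#' Construct a tissue-class generator specification
#'
#' Builds a [TissueClassSpec-class] with class-specific defaults that encode
#' the study's reported structure: gland planes carry bright cell nests
#' inside a connective scaffold while adenomas show homogeneous single-cell
#' texture; the gonadotroph-like class carries elongated papillary SHG
#' ridges; redox-ratio means/sds follow the reported per-class values; and
#' Raman band amplitudes encode the reported ratio orderings
#' (proteins/collagen elevated in all adenoma subtypes, lipids/DNA elevated
#' in all but the corticotroph-like subtype, lipids/carotenoids lower in
#' adenomas).
#'
#' @param class_name one of [pituitaryClasses()].
#' @param nest_density expected cell-nest count per plane (gland only).
#' @param rim_thickness_px connective-rim width in pixels.
#' @param papillary_elongation anisotropy factor >= 1 for SHG ridges.
#' @param redox_mean,redox_sd ground-truth NADH/(NADH+FAD) mean in (0,1)
#'   and its between-plane sd.
#' @param band_amplitudes named numeric vector of relative band amplitudes;
#'   names must be centers from `ramanBandCatalog()`.
#' @param baseline_coeffs fluorescence-baseline polynomial coefficients
#'   (ascending degree) in t = (wavenumber - 1850)/1250.
#' @param noise_sd additive Gaussian noise sd (images and spectra).
#' @return a [TissueClassSpec-class] object.
#' @export
#' @examples
#' tissueClassSpec("gland")
#' tissueClassSpec("lactotroph", noise_sd = 0)
tissueClassSpec <- function(class_name,
                            nest_density = NULL,
                            rim_thickness_px = NULL,
                            papillary_elongation = NULL,
                            redox_mean = NULL,
                            redox_sd = NULL,
                            band_amplitudes = NULL,
                            baseline_coeffs = c(3, 1.2, 0.8, -0.4, 0.3, 0.1),
                            noise_sd = 0.05) {
  if (!class_name %in% pituitaryClasses())
    stop(sprintf("unknown class_name '%s'", class_name))
  d <- .classDefaults()[[class_name]]
  new("TissueClassSpec",
      className = class_name,
      nestDensity = if (is.null(nest_density)) d$nest else nest_density,
      rimThickness = if (is.null(rim_thickness_px)) d$rim else rim_thickness_px,
      papillaryElongation = if (is.null(papillary_elongation)) d$elong
                            else papillary_elongation,
      redoxMean = if (is.null(redox_mean)) d$redox[1] else redox_mean,
      redoxSd = if (is.null(redox_sd)) d$redox[2] else redox_sd,
      bandAmplitudes = if (is.null(band_amplitudes)) d$bands
                       else band_amplitudes,
      baselineCoeffs = baseline_coeffs,
      noiseSd = noise_sd)
}

## Per-class generator defaults. Redox means/sds follow the reported
## class values (gland 0.40+/-0.11, lactotroph 0.74+/-0.08, null cell
## 0.85+/-0.08, gonadotroph 0.57+/-0.05, (mammo)somatotroph 0.77+/-0.09,
## corticotroph 0.86+/-0.10). Band amplitudes are relative units chosen so
## the three diagnostic ratios order as reported.
.classDefaults <- function() {
  band <- function(...) {
    v <- c(...)
    stats::setNames(v, as.character(ramanBandCatalog()$center))
  }
  list(
    gland = list(nest = 12, rim = 3, elong = 1, redox = c(0.40, 0.11),
      bands = band(0.30, 0.50, 0.45, 0.35, 0.35, 0.25, 0.25, 0.45, 0.60,
                   0.60, 0.35, 0.55, 0.70, 1.00)),
    lactotroph = list(nest = 0, rim = 0, elong = 1, redox = c(0.74, 0.08),
      bands = band(0.30, 0.45, 0.30, 0.35, 0.55, 0.25, 0.25, 0.40, 0.38,
                   0.95, 0.80, 0.70, 0.85, 1.00)),
    null_cell = list(nest = 0, rim = 0, elong = 1, redox = c(0.85, 0.08),
      bands = band(0.30, 0.40, 0.35, 0.30, 0.25, 0.45, 0.40, 0.40, 0.32,
                   0.88, 0.78, 0.62, 0.75, 1.00)),
    gonadotroph = list(nest = 0, rim = 0, elong = 4, redox = c(0.57, 0.05),
      bands = band(0.30, 0.48, 0.60, 0.35, 0.35, 0.25, 0.25, 0.55, 0.42,
                   0.80, 0.72, 0.66, 0.70, 1.00)),
    somatotroph_mammosomatotroph = list(nest = 0, rim = 0, elong = 1,
      redox = c(0.77, 0.09),
      bands = band(0.30, 0.42, 0.40, 0.55, 0.35, 0.25, 0.25, 0.45, 0.36,
                   1.00, 0.85, 0.72, 0.95, 1.00)),
    corticotroph = list(nest = 0, rim = 0, elong = 1, redox = c(0.86, 0.10),
      bands = band(0.45, 0.48, 0.40, 0.35, 0.45, 0.25, 0.15, 0.45, 0.34,
                   0.58, 0.60, 0.68, 0.70, 1.00)))
}

#' @rdname tissueClassSpec
#' @param noise_sd_all noise sd applied to every class spec.
#' @return `defaultClassSpecs()`: named list of six [TissueClassSpec-class].
#' @export
defaultClassSpecs <- function(noise_sd_all = 0.05) {
  specs <- lapply(pituitaryClasses(), tissueClassSpec,
                  noise_sd = noise_sd_all)
  stats::setNames(specs, pituitaryClasses())
}

## Wobbly-ellipse tissue support covering most of the frame.
.tissueSupport <- function(nr, nc) {
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  a <- 0.46 * nr; b <- 0.46 * nc
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  th <- atan2(y - cy, x - cx)
  scale <- 1 + 0.07 * sin(3 * th + p1) + 0.04 * sin(5 * th + p2)
  ((y - cy) / (a * scale))^2 + ((x - cx) / (b * scale))^2 <= 1
}

#' Generate one synthetic co-registered multimodal plane
#'
#' Simulates the OCT, TPEF, SHG and MPM images plus NADH/FAD channels and
#' tissue mask of a single 2D plane. Gland planes contain Poisson-sampled
#' cell nests (clusters of bright TPEF cell discs) enclosed by annular SHG
#' connective rims; adenoma planes carry a spatially stationary single-cell
#' texture; gonadotroph-like planes add elongated papillary SHG ridges. The
#' OCT channel is a smoothed tissue-density map with multiplicative
#' unit-mean gamma speckle. The identities MPM = SHG + TPEF and
#' TPEF = NADH + FAD hold exactly; the NADH fraction of the clean TPEF
#' signal equals a per-plane redox ratio drawn from
#' N(redox_mean, redox_sd).
#'
#' @param spec a [TissueClassSpec-class].
#' @param shape integer c(rows, cols), each >= 32 (default 128 x 128).
#' @param seed integer; identical (spec, seed) give identical planes.
#' @param plane_id,biopsy_id identifiers stored on the plane.
#' @param depth_um acquisition depth in micrometers.
#' @param acquisition named list with elements `nadh` and `fad`, each a
#'   numeric vector with `laser_power`, `gain`, `detector_response` (all
#'   positive); stored channel images are the ideal signal times
#'   laser_power^2 * gain * detector_response.
#' @return a [MultimodalPlane-class].
#' @export
#' @examples
#' sp <- tissueClassSpec("gland", noise_sd = 0)
#' pl <- generatePlane(sp, shape = c(64, 64), seed = 1)
#' pl
generatePlane <- function(spec, shape = c(128, 128), seed = 1,
                          plane_id = "plane1", biopsy_id = "biopsy1",
                          depth_um = 30,
                          acquisition = list(
                            nadh = c(laser_power = 1, gain = 1,
                                     detector_response = 1),
                            fad = c(laser_power = 1, gain = 1,
                                    detector_response = 1))) {
  validObject(spec)
  if (any(shape < 32)) stop("shape must be at least 32 x 32")
  fac <- unlist(acquisition)
  if (any(fac <= 0)) stop("acquisition factors must be positive")
  nr <- shape[1]; nc <- shape[2]
  withSeed(seed, {
    mask <- .tissueSupport(nr, nc)
    tpef <- matrix(0, nr, nc); shg <- matrix(0, nr, nc)
    tpef[mask] <- 0.25
    shg[mask] <- 0.08
    maskIdx <- which(mask, arr.ind = TRUE)
    if (spec@className == "gland") {
      nNest <- max(1L, rpois(1, spec@nestDensity))
      ctr <- maskIdx[sample.int(nrow(maskIdx), nNest), , drop = FALSE]
      for (k in seq_len(nNest)) {
        R <- runif(1, 8, 14)
        nCells <- round(0.55 * pi * R^2 / (pi * 2.2^2))
        ang <- runif(nCells, 0, 2 * pi)
        rad <- R * 0.85 * sqrt(runif(nCells))
        tpef <- stampDiscs(tpef, ctr[k, 2] + rad * cos(ang),
                           ctr[k, 1] + rad * sin(ang),
                           runif(nCells, 1.8, 2.6), 1.1)
        if (spec@rimThickness > 0) {
          th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * R))
          shg <- stampDiscs(shg, ctr[k, 2] + (R + spec@rimThickness / 2) *
                              cos(th),
                            ctr[k, 1] + (R + spec@rimThickness / 2) *
                              sin(th),
                            spec@rimThickness / 2 + 0.6, 0.9 / 2)
        }
      }
      tpef <- gaussianBlur(tpef, 0.6)
      shg <- gaussianBlur(shg, 0.8)
    } else {
      nCells <- round(0.30 * nrow(maskIdx) / (pi * 2^2))
      pos <- maskIdx[sample.int(nrow(maskIdx), nCells, replace = TRUE), ,
                     drop = FALSE]
      tpef <- stampDiscs(tpef, pos[, 2], pos[, 1],
                         runif(nCells, 1.6, 2.2), 0.45)
      tpef <- gaussianBlur(tpef, 1.2)
      if (spec@papillaryElongation > 1) {
        nRidge <- 9L
        rc <- maskIdx[sample.int(nrow(maskIdx), nRidge), , drop = FALSE]
        for (k in seq_len(nRidge))
          shg <- stampRidge(shg, rc[k, 2], rc[k, 1],
                            runif(1, 0, pi),
                            3 * spec@papillaryElongation, 2, 0.9)
      } else {
        nBlob <- 40L
        bc <- maskIdx[sample.int(nrow(maskIdx), nBlob), , drop = FALSE]
        shg <- stampDiscs(shg, bc[, 2], bc[, 1], runif(nBlob, 2, 4), 0.2)
        shg <- gaussianBlur(shg, 1.5)
      }
    }
    tpef[!mask] <- 0; shg[!mask] <- 0
    ## metabolic split of the clean TPEF signal
    redox <- clamp(rnorm(1, spec@redoxMean, spec@redoxSd), 0.02, 0.98)
    nadh <- redox * tpef
    fad <- (1 - redox) * tpef
    ## OCT: refractive-index-correlated density map with gamma speckle
    dens <- gaussianBlur(tpef + 1.5 * shg, 2)
    oct <- (0.3 + dens) * matrix(rgamma(nr * nc, shape = 16, rate = 16),
                                 nr, nc)
    oct[!mask] <- 0
    if (spec@noiseSd > 0) {
      ## shot-noise-like channel noise: sd scales with sqrt(intensity),
      ## as for photon-counting detectors; keeps zero-clipping negligible
      ## at low intensities so channel means stay unbiased
      addNoise <- function(m) {
        mu <- m[mask]
        m[mask] <- pmax(0, mu + rnorm(sum(mask), 0,
                                      spec@noiseSd * sqrt(pmax(mu, 0))))
        m
      }
      nadh <- addNoise(nadh); fad <- addNoise(fad)
      shg <- addNoise(shg); oct <- addNoise(oct)
    }
    nfac <- acquisition$nadh; ffac <- acquisition$fad
    nadh <- nadh * nfac[["laser_power"]]^2 * nfac[["gain"]] *
      nfac[["detector_response"]]
    fad <- fad * ffac[["laser_power"]]^2 * ffac[["gain"]] *
      ffac[["detector_response"]]
    tpefOut <- nadh + fad
    new("MultimodalPlane",
        planeId = plane_id, biopsyId = biopsy_id,
        className = spec@className,
        binaryLabel = if (spec@className == "gland") "gland" else "adenoma",
        depthUm = depth_um,
        images = list(OCT = oct, TPEF = tpefOut, SHG = shg,
                      MPM = shg + tpefOut),
        nadh = nadh, fad = fad, mask = mask,
        acquisition = acquisition)
  })
}

## Gaussian band width in cm^-1: broader for the two C-H stretch bands.
.bandSigma <- function(center) ifelse(center >= 2800, 12, 8)

#' Ideal (noise- and baseline-free) spectrum of a class specification
#'
#' The generator's ground truth: a sum of Gaussian bands at the catalog
#' centers with the spec's amplitudes. `idealBandIntensity()` returns its
#' mean over a +/- `halfwidth` window around `center`, the quantity the
#' band-ratio estimators target.
#'
#' @param spec a [TissueClassSpec-class].
#' @param axis wavenumber axis (cm^-1).
#' @param include_baseline include the fluorescence baseline polynomial.
#' @return numeric vector along `axis`.
#' @export
idealSpectrum <- function(spec, axis = seq(600, 3100, by = 1),
                          include_baseline = FALSE) {
  s <- numeric(length(axis))
  centers <- as.numeric(names(spec@bandAmplitudes))
  for (i in seq_along(centers)) {
    sig <- .bandSigma(centers[i])
    s <- s + spec@bandAmplitudes[i] *
      exp(-(axis - centers[i])^2 / (2 * sig^2))
  }
  if (include_baseline) {
    t <- (axis - 1850) / 1250
    s <- s + drop(outer(t, seq_along(spec@baselineCoeffs) - 1, `^`) %*%
                    spec@baselineCoeffs)
  }
  s
}

#' @rdname idealSpectrum
#' @param center band center in cm^-1.
#' @param halfwidth window half-width in cm^-1.
#' @export
idealBandIntensity <- function(spec, center, halfwidth = 5,
                               axis = seq(600, 3100, by = 1)) {
  s <- idealSpectrum(spec, axis)
  mean(s[abs(axis - center) <= halfwidth])
}

#' Generate a synthetic line-scan Raman map
#'
#' Each position's spectrum is the class's ideal band mixture scaled by a
#' per-position log-normal intensity factor, plus the fluorescence baseline
#' polynomial and additive Gaussian noise, clipped at zero. With
#' `noise_sd = 0` every spectrum equals the ideal spectrum plus baseline
#' exactly.
#'
#' @param spec a [TissueClassSpec-class].
#' @param n_positions number of line-scan positions (default 2100, the
#'   typical per-biopsy spectra count).
#' @param seed integer seed.
#' @param axis wavenumber axis, strictly increasing (cm^-1).
#' @param map_id identifier.
#' @return a [RamanMap-class].
#' @export
#' @examples
#' sp <- tissueClassSpec("gland", noise_sd = 0)
#' m <- generateRamanMap(sp, n_positions = 5, seed = 1)
#' m
generateRamanMap <- function(spec, n_positions = 2100, seed = 1,
                             axis = seq(600, 3100, by = 1),
                             map_id = "map1") {
  validObject(spec)
  if (n_positions < 1) stop("n_positions must be >= 1")
  ideal <- idealSpectrum(spec, axis)
  t <- (axis - 1850) / 1250
  base <- drop(outer(t, seq_along(spec@baselineCoeffs) - 1, `^`) %*%
                 spec@baselineCoeffs)
  withSeed(seed, {
    fac <- if (spec@noiseSd > 0)
      exp(rnorm(n_positions, 0, spec@noiseSd)) else rep(1, n_positions)
    spec_mat <- outer(fac, ideal) +
      matrix(base, n_positions, length(axis), byrow = TRUE)
    if (spec@noiseSd > 0)
      spec_mat <- spec_mat + matrix(rnorm(length(spec_mat), 0,
                                          spec@noiseSd),
                                    n_positions)
    spec_mat <- pmax(spec_mat, 0)
    new("RamanMap", mapId = map_id, className = spec@className,
        wavenumbers = axis, spectra = spec_mat,
        positions = seq_len(n_positions))
  })
}

#' Default cohort composition
#'
#' The study composition: 174 planes in total, 25 gland planes from 5 gland
#' biopsies (5 planes each) and 149 adenoma planes from 25 adenoma biopsies
#' (5 subtypes x 5 biopsies, 6 planes each except the final corticotroph
#' biopsy with 5).
#'
#' @return data.frame with columns `biopsy_id`, `class_name`, `n_planes`.
#' @export
defaultComposition <- function() {
  rows <- list()
  for (b in 1:5)
    rows[[length(rows) + 1L]] <-
      data.frame(biopsy_id = sprintf("gland_b%d", b),
                 class_name = "gland", n_planes = 5L)
  adeno <- setdiff(pituitaryClasses(), "gland")
  for (cl in adeno) for (b in 1:5) {
    n <- if (cl == "corticotroph" && b == 5) 5L else 6L
    rows[[length(rows) + 1L]] <-
      data.frame(biopsy_id = sprintf("%s_b%d", cl, b),
                 class_name = cl, n_planes = n)
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic cohort
#'
#' Generates multimodal planes (grouped by biopsy) and one Raman map per
#' biopsy according to a composition table. The default composition yields
#' 174 planes (25 gland, 149 adenoma).
#'
#' @param class_specs named list of [TissueClassSpec-class], one per class
#'   appearing in the composition.
#' @param composition data.frame as returned by [defaultComposition()].
#' @param seed integer master seed; all per-plane and per-map seeds derive
#'   from it.
#' @param shape plane shape (default 128 x 128).
#' @param raman_positions line-scan positions per biopsy map (0 disables
#'   Raman map generation).
#' @param raman_axis wavenumber axis for the maps.
#' @return a [PituitaryCohort-class].
#' @export
#' @examples
#' co <- generateCohort(composition = data.frame(
#'   biopsy_id = "g1", class_name = "gland", n_planes = 1),
#'   seed = 1, shape = c(48, 48), raman_positions = 0)
#' co
generateCohort <- function(class_specs = defaultClassSpecs(),
                           composition = defaultComposition(),
                           seed = 1, shape = c(128, 128),
                           raman_positions = 200,
                           raman_axis = seq(600, 3100, by = 1)) {
  need <- unique(composition$class_name)
  if (!all(need %in% names(class_specs)))
    stop("class_specs missing for: ",
         paste(setdiff(need, names(class_specs)), collapse = ", "))
  counts <- table(composition$class_name)
  if (any(counts < 1)) stop("every requested class needs >= 1 biopsy")
  planes <- list(); maps <- list()
  saltP <- 0L
  for (i in seq_len(nrow(composition))) {
    bid <- composition$biopsy_id[i]
    cl <- composition$class_name[i]
    sp <- class_specs[[cl]]
    for (k in seq_len(composition$n_planes[i])) {
      saltP <- saltP + 1L
      pid <- sprintf("%s_p%02d", bid, k)
      planes[[pid]] <- generatePlane(
        sp, shape = shape, seed = deriveSeed(seed, saltP),
        plane_id = pid, biopsy_id = bid, depth_um = (k - 1) * 30)
    }
    if (raman_positions > 0) {
      maps[[bid]] <- generateRamanMap(
        sp, n_positions = raman_positions,
        seed = deriveSeed(seed, 100000L + i),
        axis = raman_axis, map_id = paste0(bid, "_map"))
    }
  }
  new("PituitaryCohort", planes = planes, ramanMaps = maps,
      seed = as.integer(seed), generatorTruth = class_specs[need])
}
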