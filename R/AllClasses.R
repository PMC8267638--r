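#' Tissue classes and Raman band catalog
#'
#' `pituitaryClasses()` returns the six tissue classes handled by the
#' package: healthy pituitary gland plus the five adenoma subtypes
#' (lactotroph, null cell, gonadotroph, somatotroph/mammosomatotroph,
#' corticotroph). `ramanBandCatalog()` returns the reference set of
#' vibrational band centers (cm^-1) with their biochemical assignments
#' (DNA, collagen, proteins, lipids, carotenoids, C-H stretches).
#'
#' @return `pituitaryClasses()`: character vector of length 6.
#'   `ramanBandCatalog()`: data.frame with columns `center` and
#'   `assignment`.
#' @export
#' @examples
#' pituitaryClasses()
#' ramanBandCatalog()
pituitaryClasses <- function() {
  c("gland", "lactotroph", "null_cell", "gonadotroph",
    "somatotroph_mammosomatotroph", "corticotroph")
}

#' @rdname pituitaryClasses
#' @export
ramanBandCatalog <- function() {
  data.frame(
    center = c(678, 720, 855, 937, 1004, 1093, 1160, 1254, 1335, 1445,
               1520, 1660, 2873, 2940),
    assignment = c(
      "DNA ring breathing", "DNA",
      "tyrosine/protein/collagen", "protein/collagen backbone",
      "phenylalanine", "nucleic acids/phospholipids",
      "proteins/tyrosine", "protein/collagen (amide III)",
      "collagen/protein", "fatty acids/protein/lipid",
      "carotenoids", "unsaturated fatty acids/protein/lipids (amide I)",
      "lipids (CH2)", "proteins/lipids (CH3)"),
    stringsAsFactors = FALSE)
}

planeModalities <- function() c("OCT", "TPEF", "SHG", "MPM")

#' TissueClassSpec: ground-truth generator parameters for one tissue class
#'
#' Encodes the morphological (cell-nest density, connective rim thickness,
#' papillary elongation), metabolic (optical redox ratio mean and
#' between-plane sd) and molecular (Raman band amplitudes on a fluorescence
#' baseline) ground truth used by the synthetic cohort generator.
#'
#' @slot className one of [pituitaryClasses()].
#' @slot nestDensity expected cell-nest count per plane (gland morphology).
#' @slot rimThickness connective-rim width in pixels.
#' @slot papillaryElongation anisotropy factor >= 1 for elongated SHG
#'   structures (gonadotroph-like papillary pattern).
#' @slot redoxMean ground-truth NADH/(NADH+FAD) in (0, 1).
#' @slot redoxSd between-plane standard deviation of the redox ratio.
#' @slot bandAmplitudes named numeric: relative amplitude per Raman band
#'   center; names must belong to `ramanBandCatalog()$center`.
#' @slot baselineCoeffs polynomial coefficients (ascending degree) of the
#'   fluorescence background in the scaled coordinate
#'   t = (wavenumber - 1850)/1250.
#' @slot noiseSd additive Gaussian noise sd for images and spectra.
#' @export
setClass("TissueClassSpec", representation(
  className = "character",
  nestDensity = "numeric",
  rimThickness = "numeric",
  papillaryElongation = "numeric",
  redoxMean = "numeric",
  redoxSd = "numeric",
  bandAmplitudes = "numeric",
  baselineCoeffs = "numeric",
  noiseSd = "numeric"))

setValidity("TissueClassSpec", function(object) {
  msg <- character()
  if (!object@className %in% pituitaryClasses())
    msg <- c(msg, sprintf("unknown class_name '%s'", object@className))
  if (object@redoxMean <= 0 || object@redoxMean >= 1)
    msg <- c(msg, "redoxMean must lie in (0, 1)")
  if (object@redoxSd < 0) msg <- c(msg, "redoxSd must be >= 0")
  if (object@nestDensity < 0) msg <- c(msg, "nestDensity must be >= 0")
  if (object@rimThickness < 0) msg <- c(msg, "rimThickness must be >= 0")
  if (object@papillaryElongation < 1)
    msg <- c(msg, "papillaryElongation must be >= 1")
  if (any(object@bandAmplitudes < 0))
    msg <- c(msg, "band amplitudes must be >= 0")
  known <- as.character(ramanBandCatalog()$center)
  if (!all(names(object@bandAmplitudes) %in% known))
    msg <- c(msg, "band centers must come from ramanBandCatalog()")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MultimodalPlane: one co-registered 2D multimodal sample
#'
#' Holds the four co-registered modality images (OCT, TPEF, SHG, MPM) of a
#' single 2D plane together with the NADH and FAD fluorescence channels,
#' the tissue mask and acquisition factors. Construction enforces the
#' co-registration identities MPM = SHG + TPEF and TPEF = NADH + FAD.
#'
#' @slot planeId,biopsyId character identifiers.
#' @slot className tissue class; @slot binaryLabel "gland" or "adenoma".
#' @slot depthUm acquisition depth in micrometers.
#' @slot images named list of 4 nonnegative matrices (OCT, TPEF, SHG, MPM).
#' @slot nadh,fad nonnegative matrices, same shape as the images.
#' @slot mask logical matrix, same shape; the tissue-bearing region.
#' @slot acquisition named list per channel (nadh, fad) of
#'   laser_power/gain/detector_response factors, all positive.
#' @export
setClass("MultimodalPlane", representation(
  planeId = "character", biopsyId = "character",
  className = "character", binaryLabel = "character",
  depthUm = "numeric", images = "list",
  nadh = "matrix", fad = "matrix", mask = "matrix",
  acquisition = "list"))

setValidity("MultimodalPlane", function(object) {
  msg <- character()
  if (!setequal(names(object@images), planeModalities()))
    msg <- c(msg, "images must be named OCT, TPEF, SHG, MPM")
  dims <- lapply(c(object@images, list(object@nadh, object@fad,
                                       object@mask)), dim)
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "all images and the mask must share one shape")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  else if (!any(object@mask)) msg <- c(msg, "mask must have >= 1 TRUE pixel")
  if (any(vapply(object@images, function(m) any(m < 0), logical(1))))
    msg <- c(msg, "modality images must be nonnegative")
  if (!length(msg)) {
    ## tolerance admits storage roundtrips (32-bit float TIFF); generated
    ## planes satisfy the identities exactly
    if (max(abs(object@images$MPM -
                  (object@images$SHG + object@images$TPEF))) > 1e-5)
      msg <- c(msg, "MPM must equal SHG + TPEF pixelwise")
    if (max(abs(object@images$TPEF - (object@nadh + object@fad))) > 1e-5)
      msg <- c(msg, "TPEF must equal NADH + FAD pixelwise")
  }
  if (!object@binaryLabel %in% c("gland", "adenoma"))
    msg <- c(msg, "binaryLabel must be 'gland' or 'adenoma'")
  fac <- unlist(object@acquisition)
  if (length(fac) && any(fac <= 0))
    msg <- c(msg, "acquisition factors must be > 0")
  if (object@depthUm < 0) msg <- c(msg, "depthUm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' RamanMap: a line-scan hyperspectral block
#'
#' Spectra collected along a scanned laser line: one row per position,
#' one column per wavenumber.
#'
#' @slot mapId character identifier.
#' @slot className tissue class of the mapped biopsy.
#' @slot wavenumbers strictly increasing axis in cm^-1.
#' @slot spectra positions x wavenumbers matrix (nonnegative for raw maps).
#' @slot positions integer step indices along the scanned line.
#' @export
setClass("RamanMap", representation(
  mapId = "character", className = "character",
  wavenumbers = "numeric", spectra = "matrix", positions = "integer"))

setValidity("RamanMap", function(object) {
  msg <- character()
  if (ncol(object@spectra) != length(object@wavenumbers))
    msg <- c(msg, "spectra column count must equal wavenumber count")
  if (is.unsorted(object@wavenumbers, strictly = TRUE))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (nrow(object@spectra) != length(object@positions))
    msg <- c(msg, "one position index per spectrum required")
  if (length(msg)) msg else TRUE
})

#' PituitaryCohort: a full synthetic study cohort
#'
#' @slot planes list of [MultimodalPlane-class] objects.
#' @slot ramanMaps list of [RamanMap-class] objects (one or more per biopsy).
#' @slot seed integer seed the cohort was generated from.
#' @slot generatorTruth named list of [TissueClassSpec-class] used.
#' @export
setClass("PituitaryCohort", representation(
  planes = "list", ramanMaps = "list", seed = "integer",
  generatorTruth = "list"))

#' SpectralPCA: a fitted principal-component model for spectra
#'
#' @slot center mean spectrum.
#' @slot loadings wavenumbers x components matrix, ordered by explained
#'   variance.
#' @slot varianceExplained fraction of variance per retained component.
#' @slot nComponents number of retained components.
#' @export
setClass("SpectralPCA", representation(
  center = "numeric", loadings = "matrix",
  varianceExplained = "numeric", nComponents = "integer"))

setValidity("SpectralPCA", function(object) {
  v <- object@varianceExplained
  msg <- character()
  if (any(v < 0 | v > 1)) msg <- c(msg, "variance fractions must be in [0,1]")
  if (is.unsorted(rev(v))) msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(v) > 1 + 1e-8) msg <- c(msg, "variance fractions must sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' MulticlassReport: pooled confusion matrix and one-vs-rest metrics
#'
#' @slot confusion square confusion matrix (rows = truth, cols = predicted).
#' @slot metrics data.frame with per-class one-vs-rest accuracy,
#'   sensitivity and specificity.
#' @export
setClass("MulticlassReport", representation(
  confusion = "matrix", metrics = "data.frame"))

#' MCFoldReport: Monte-Carlo cross-validation result
#'
#' @slot folds list of per-fold results (confusion matrix, selected
#'   features, validation ids).
#' @slot pooled named numeric: pooled accuracy/sensitivity/specificity.
#' @slot perFold data.frame of per-fold metrics.
#' @slot featureFrequency named integer: how often each feature was selected.
#' @slot probabilities data.frame of per-plane mean validation
#'   adenoma-probability.
#' @slot positiveClass class treated as positive for sensitivity.
#' @export
setClass("MCFoldReport", representation(
  folds = "list", pooled = "numeric", perFold = "data.frame",
  featureFrequency = "integer", probabilities = "data.frame",
  positiveClass = "character"))

#' BiomarkerFingerprint: five-axis multiparametric biomarker per class
#'
#' Axes: radiomics binary-classification score, redox ratio, and the three
#' Raman band ratios (proteins/collagen 1660/1335, lipids/carotenoids
#' 1445/1520, lipids/DNA 1445/720).
#'
#' @slot raw classes x 5 matrix of raw axis values.
#' @slot normalized same matrix with each axis divided by its cohort maximum.
#' @export
setClass("BiomarkerFingerprint", representation(
  raw = "matrix", normalized = "matrix"))
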