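#' Accessors for multiPit classes
#'
#' Small accessor generics: `planes()` and `ramanMaps()` extract the plane
#' and map lists of a cohort, `className()` and `binaryLabel()` the tissue
#' labels, `modalityImage()` one named modality matrix, `tissueMask()` the
#' tissue mask, `nadhImage()`/`fadImage()` the metabolic channels,
#' `wavenumbers()` and `spectra()` the axis and matrix of a Raman map.
#'
#' @param object a multiPit S4 object.
#' @param modality one of "OCT", "TPEF", "SHG", "MPM".
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("planes", function(object) standardGeneric("planes"))
#' @rdname accessors
#' @export
setGeneric("ramanMaps", function(object) standardGeneric("ramanMaps"))
#' @rdname accessors
#' @export
setGeneric("className", function(object) standardGeneric("className"))
#' @rdname accessors
#' @export
setGeneric("binaryLabel", function(object) standardGeneric("binaryLabel"))
#' @rdname accessors
#' @export
setGeneric("modalityImage",
           function(object, modality) standardGeneric("modalityImage"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("nadhImage", function(object) standardGeneric("nadhImage"))
#' @rdname accessors
#' @export
setGeneric("fadImage", function(object) standardGeneric("fadImage"))
#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))

#' @rdname accessors
setMethod("planes", "PituitaryCohort", function(object) object@planes)
#' @rdname accessors
setMethod("ramanMaps", "PituitaryCohort", function(object) object@ramanMaps)
#' @rdname accessors
setMethod("className", "MultimodalPlane", function(object) object@className)
#' @rdname accessors
setMethod("className", "RamanMap", function(object) object@className)
#' @rdname accessors
setMethod("className", "TissueClassSpec", function(object) object@className)
#' @rdname accessors
setMethod("binaryLabel", "MultimodalPlane", function(object) object@binaryLabel)
#' @rdname accessors
setMethod("modalityImage", "MultimodalPlane", function(object, modality) {
  modality <- match.arg(modality, planeModalities())
  object@images[[modality]]
})
#' @rdname accessors
setMethod("tissueMask", "MultimodalPlane", function(object) object@mask)
#' @rdname accessors
setMethod("nadhImage", "MultimodalPlane", function(object) object@nadh)
#' @rdname accessors
setMethod("fadImage", "MultimodalPlane", function(object) object@fad)
#' @rdname accessors
setMethod("wavenumbers", "RamanMap", function(object) object@wavenumbers)
#' @rdname accessors
setMethod("spectra", "RamanMap", function(object) object@spectra)

setMethod("show", "TissueClassSpec", function(object) {
  cat("TissueClassSpec:", object@className, "\n")
  cat("  redox ratio:", sprintf("%.2f +/- %.2f", object@redoxMean,
                                object@redoxSd), "\n")
  cat("  nests/plane:", object@nestDensity,
      " rim px:", object@rimThickness,
      " elongation:", object@papillaryElongation, "\n")
  cat("  Raman bands:", length(object@bandAmplitudes),
      " noise sd:", object@noiseSd, "\n")
})

setMethod("show", "MultimodalPlane", function(object) {
  d <- dim(object@mask)
  cat(sprintf("MultimodalPlane %s (%s, %s) %dx%d, depth %.0f um\n",
              object@planeId, object@className, object@binaryLabel,
              d[1], d[2], object@depthUm))
})

setMethod("show", "RamanMap", function(object) {
  cat(sprintf("RamanMap %s (%s): %d spectra x %d wavenumbers (%g-%g cm-1)\n",
              object@mapId, object@className, nrow(object@spectra),
              ncol(object@spectra), min(object@wavenumbers),
              max(object@wavenumbers)))
})

setMethod("show", "PituitaryCohort", function(object) {
  lab <- vapply(object@planes, binaryLabel, character(1))
  cat(sprintf("PituitaryCohort: %d planes (%d gland, %d adenoma), %d Raman maps, seed %d\n",
              length(object@planes), sum(lab == "gland"),
              sum(lab == "adenoma"), length(object@ramanMaps), object@seed))
})

setMethod("show", "SpectralPCA", function(object) {
  cat(sprintf("SpectralPCA: %d components, %.1f%% variance explained\n",
              object@nComponents, 100 * sum(object@varianceExplained)))
})

setMethod("show", "MulticlassReport", function(object) {
  cat("MulticlassReport\n")
  print(round(object@metrics, 3))
})

setMethod("show", "MCFoldReport", function(object) {
  cat(sprintf("MCFoldReport: %d folds, positive class '%s'\n",
              length(object@folds), object@positiveClass))
  cat(sprintf("  pooled accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              object@pooled["accuracy"], object@pooled["sensitivity"],
              object@pooled["specificity"]))
})

setMethod("show", "BiomarkerFingerprint", function(object) {
  cat("BiomarkerFingerprint (normalized axes)\n")
  print(round(object@normalized, 3))
})
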