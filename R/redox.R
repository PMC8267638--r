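#' Corrected mean channel intensity
#'
#' Mean masked intensity divided by the acquisition factors: laser power
#' (squared by default, reflecting the quadratic two-photon excitation
#' dependence), gain and detector spectral response.
#'
#' @param image 2D channel image.
#' @param mask logical matrix; at least one TRUE pixel.
#' @param laser_power,gain,detector_response positive correction factors.
#' @param power_exponent 2 for two-photon excitation (default); 1 for a
#'   linear correction.
#' @return nonnegative scalar.
#' @export
#' @examples
#' correctedIntensity(matrix(8, 4, 4), matrix(TRUE, 4, 4),
#'                    laser_power = 2, gain = 1, detector_response = 1)  # 2
correctedIntensity <- function(image, mask, laser_power, gain,
                               detector_response, power_exponent = 2) {
  if (!any(mask)) stop("empty mask")
  if (laser_power <= 0 || gain <= 0 || detector_response <= 0)
    stop("correction factors must be > 0")
  mean(image[mask]) / (laser_power^power_exponent * gain *
                         detector_response)
}

#' Optical redox ratio
#'
#' NADH/(NADH + FAD) from corrected channel intensities; invariant to any
#' common multiplicative factor and strictly increasing in NADH.
#'
#' @param nadh_corrected,fad_corrected corrected channel intensities,
#'   nadh + fad > 0.
#' @return ratio in [0, 1].
#' @export
redoxRatio <- function(nadh_corrected, fad_corrected) {
  if (nadh_corrected + fad_corrected <= 0)
    stop("NADH + FAD must be > 0")
  nadh_corrected / (nadh_corrected + fad_corrected)
}

#' Per-plane redox measurements for a cohort
#'
#' Computes the corrected NADH and FAD mean intensities (using each
#' plane's stored acquisition factors and tissue mask) and the redox ratio
#' per plane.
#'
#' @param cohort a [PituitaryCohort-class].
#' @param power_exponent passed to [correctedIntensity()].
#' @return data.frame with `plane_id`, `class_name`, `nadh`, `fad`,
#'   `ratio`.
#' @export
redoxTable <- function(cohort, power_exponent = 2) {
  rows <- lapply(planes(cohort), function(p) {
    nf <- p@acquisition$nadh; ff <- p@acquisition$fad
    nadh <- correctedIntensity(p@nadh, p@mask, nf[["laser_power"]],
                               nf[["gain"]], nf[["detector_response"]],
                               power_exponent)
    fad <- correctedIntensity(p@fad, p@mask, ff[["laser_power"]],
                              ff[["gain"]], ff[["detector_response"]],
                              power_exponent)
    data.frame(plane_id = p@planeId, class_name = p@className,
               nadh = nadh, fad = fad, ratio = redoxRatio(nadh, fad),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group statistics of the redox ratio
#'
#' Shapiro-Wilk normality per class, group mean and sd in "mean +/- sd"
#' form, and a two-tailed Welch's t-test of each adenoma class against the
#' reference (gland) group. Groups below the minimum size are skipped with
#' a message.
#'
#' @param redox data.frame with columns `class_name` and `ratio` (as from
#'   [redoxTable()]).
#' @param reference reference class (default "gland").
#' @param min_n minimum group size for testing (default 3).
#' @return data.frame with per-class n, mean, sd, `shapiro_p` and
#'   `welch_p` (NA for the reference row).
#' @export
compareRedoxGroups <- function(redox, reference = "gland", min_n = 3) {
  stopifnot(reference %in% redox$class_name)
  ref <- redox$ratio[redox$class_name == reference]
  cls <- unique(redox$class_name)
  rows <- lapply(cls, function(cl) {
    v <- redox$ratio[redox$class_name == cl]
    if (length(v) < min_n) {
      message("compareRedoxGroups: skipping group '", cl,
              "' (n < ", min_n, ")")
      return(NULL)
    }
    sw <- if (length(v) >= 3 && stats::sd(v) > 0)
      stats::shapiro.test(v)$p.value else NA_real_
    wp <- if (cl == reference) NA_real_
    else if (stats::sd(v) == 0 && stats::sd(ref) == 0 &&
               mean(v) == mean(ref)) 1
    else stats::t.test(v, ref, var.equal = FALSE)$p.value
    data.frame(class_name = cl, n = length(v), mean = mean(v),
               sd = stats::sd(v), shapiro_p = sw, welch_p = wp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
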