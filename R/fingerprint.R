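.fingerprintAxes <- function() {
  c("radiomics_binary", "redox_ratio", "proteins_collagen",
    "lipids_carotenoids", "lipids_dna")
}

#' Assemble the five-axis multiparametric biomarker fingerprint
#'
#' Combines, per tissue class: (1) the radiomics binary-classification
#' score (mean predicted adenoma-probability of the class's planes across
#' the MC folds in which they were validated), (2) the mean redox ratio,
#' and (3-5) the three Raman ratio means (proteins/collagen 1660/1335,
#' lipids/carotenoids 1445/1520, lipids/DNA 1445/720). Each axis is also
#' normalized by its maximum over classes for spider-plot display.
#'
#' @param mc_report an [MCFoldReport-class] from [runMCCV()].
#' @param redox data.frame from [redoxTable()].
#' @param ratios data.frame from [ratioTable()].
#' @return a [BiomarkerFingerprint-class]; classes missing from any input
#'   are flagged with a warning and carried as NA.
#' @export
buildFingerprint <- function(mc_report, redox, ratios) {
  cls <- pituitaryClasses()
  axes <- .fingerprintAxes()
  raw <- matrix(NA_real_, length(cls), length(axes),
                dimnames = list(cls, axes))
  pb <- mc_report@probabilities
  for (cl in cls) {
    sel <- pb$class_name == cl & pb$n_validations > 0
    if (any(sel))
      raw[cl, "radiomics_binary"] <- mean(pb$mean_prob_positive[sel])
    rsel <- redox$class_name == cl
    if (any(rsel)) raw[cl, "redox_ratio"] <- mean(redox$ratio[rsel])
    tsel <- ratios$class_name == cl
    if (any(tsel)) {
      raw[cl, "proteins_collagen"] <- mean(ratios$R1[tsel], na.rm = TRUE)
      raw[cl, "lipids_carotenoids"] <- mean(ratios$R2[tsel], na.rm = TRUE)
      raw[cl, "lipids_dna"] <- mean(ratios$R3[tsel], na.rm = TRUE)
    }
  }
  if (anyNA(raw))
    warning("incomplete fingerprint: missing classes in at least one input")
  normalized <- sweep(raw, 2, apply(raw, 2, max, na.rm = TRUE), `/`)
  new("BiomarkerFingerprint", raw = raw, normalized = normalized)
}

## Polynomial rolling hash of a character scalar; a dependency-free
## config fingerprint (stable across sessions and platforms).
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Render fingerprint and metrics reports
#'
#' Writes a JSON bundle (fingerprints, pooled metrics, seeds, config hash),
#' a per-class fingerprint CSV, and a spider-plot figure of the normalized
#' fingerprint axes. Re-running with the same inputs produces a
#' byte-identical JSON bundle.
#'
#' @param fingerprint a [BiomarkerFingerprint-class].
#' @param reports named list of additional report objects to serialize
#'   (e.g. the pooled entries of an [MCFoldReport-class]).
#' @param out_dir output directory (created if missing).
#' @param seed seed to record in the bundle.
#' @param figure write the spider plot PNG (set FALSE for headless runs).
#' @return invisibly, the paths written.
#' @export
renderReports <- function(fingerprint, reports = list(), out_dir,
                          seed = NA_integer_, figure = TRUE) {
  if (nrow(fingerprint@raw) == 0 || all(is.na(fingerprint@raw))) {
    warning("empty fingerprint set: no reports written")
    return(invisible(character(0)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(
    fingerprint_raw = as.data.frame(fingerprint@raw),
    fingerprint_normalized = as.data.frame(fingerprint@normalized),
    reports = reports,
    seed = seed,
    package_version = as.character(utils::packageVersion("multiPit")))
  json <- jsonlite::toJSON(bundle, digits = NA, pretty = TRUE,
                           na = "null")
  bundle$config_hash <- .configHash(as.character(json))
  jsonPath <- file.path(out_dir, "report_bundle.json")
  writeLines(jsonlite::toJSON(bundle, digits = NA, pretty = TRUE,
                              na = "null"), jsonPath)
  csvPath <- file.path(out_dir, "fingerprint.csv")
  utils::write.csv(data.frame(class = rownames(fingerprint@raw),
                              fingerprint@raw, check.names = FALSE),
                   csvPath, row.names = FALSE)
  paths <- c(jsonPath, csvPath)
  if (figure) {
    figPath <- file.path(out_dir, "fingerprint_spider.png")
    grDevices::png(figPath, width = 800, height = 700)
    plotSpiderFingerprint(fingerprint)
    grDevices::dev.off()
    paths <- c(paths, figPath)
  }
  invisible(paths)
}

#' Spider plot of the normalized fingerprint
#'
#' @param fingerprint a [BiomarkerFingerprint-class].
#' @param main plot title.
#' @export
plotSpiderFingerprint <- function(fingerprint,
                                  main = "Multiparametric biomarker") {
  M <- fingerprint@normalized
  nAxes <- ncol(M)
  ang <- seq(0, 2 * pi, length.out = nAxes + 1)[-(nAxes + 1)] + pi / 2
  graphics::plot(NA, xlim = c(-1.5, 1.5), ylim = c(-1.4, 1.5),
                 axes = FALSE, xlab = "", ylab = "", main = main,
                 asp = 1)
  for (r in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey70")
  graphics::text(1.25 * cos(ang), 1.25 * sin(ang),
                 colnames(M), cex = 0.8)
  cols <- grDevices::hcl.colors(nrow(M), "Dark 3")
  for (i in seq_len(nrow(M))) {
    v <- ifelse(is.na(M[i, ]), 0, M[i, ])
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[i],
                      col = grDevices::adjustcolor(cols[i], 0.15),
                      lwd = 2)
  }
  graphics::legend("bottom", legend = rownames(M), col = cols, lwd = 2,
                   bty = "n", cex = 0.7, ncol = 2)
  invisible(NULL)
}
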