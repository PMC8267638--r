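#' Write and read a cohort on disk
#'
#' Planes are written as multi-page 32-bit float TIFF (page order OCT,
#' TPEF, SHG, MPM, NADH, FAD, mask) next to a cohort metadata CSV
#' (`cohort.csv`: plane_id, biopsy_id, class, label, depth and the
#' per-channel acquisition factors). Raman maps are written as CSV with
#' the wavenumber axis as the first row; a JSON sidecar stores the seed
#' and class names.
#'
#' @param cohort a [PituitaryCohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(planes(cohort), function(p) {
    pages <- c(p@images[planeModalities()],
               list(p@nadh, p@fad, p@mask * 1))
    ## TIFF storage is [0,1]; rescale by a per-plane factor kept in the CSV
    sc <- max(vapply(pages, max, numeric(1)), 1e-12)
    tiff::writeTIFF(lapply(pages, function(m) m / sc),
                    file.path(dir, paste0(p@planeId, ".tiff")),
                    bits.per.sample = 32L, reduce = FALSE)
    nf <- p@acquisition$nadh; ff <- p@acquisition$fad
    data.frame(plane_id = p@planeId, biopsy_id = p@biopsyId,
               class_name = p@className, label = p@binaryLabel,
               depth_um = p@depthUm, tiff_scale = sc,
               nadh_laser_power = nf[["laser_power"]],
               nadh_gain = nf[["gain"]],
               nadh_detector_response = nf[["detector_response"]],
               fad_laser_power = ff[["laser_power"]],
               fad_gain = ff[["gain"]],
               fad_detector_response = ff[["detector_response"]],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, c(meta, list(make.row.names = FALSE))),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  for (m in ramanMaps(cohort))
    writeRamanMapCSV(m, file.path(dir, paste0(m@mapId, ".csv")))
  sidecar <- list(seed = cohort@seed,
                  classes = names(cohort@generatorTruth),
                  n_planes = length(planes(cohort)),
                  n_maps = length(ramanMaps(cohort)))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "cohort.json"))
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  pls <- list()
  for (i in seq_len(nrow(meta))) {
    pid <- meta$plane_id[i]
    pages <- tiff::readTIFF(file.path(dir, paste0(pid, ".tiff")),
                            all = TRUE)
    sc <- meta$tiff_scale[i]
    pages[1:6] <- lapply(pages[1:6], function(m) m * sc)
    acq <- list(
      nadh = c(laser_power = meta$nadh_laser_power[i],
               gain = meta$nadh_gain[i],
               detector_response = meta$nadh_detector_response[i]),
      fad = c(laser_power = meta$fad_laser_power[i],
              gain = meta$fad_gain[i],
              detector_response = meta$fad_detector_response[i]))
    pls[[pid]] <- new("MultimodalPlane",
                      planeId = pid, biopsyId = meta$biopsy_id[i],
                      className = meta$class_name[i],
                      binaryLabel = meta$label[i],
                      depthUm = meta$depth_um[i],
                      images = list(OCT = pages[[1]], TPEF = pages[[2]],
                                    SHG = pages[[3]], MPM = pages[[4]]),
                      nadh = pages[[5]], fad = pages[[6]],
                      mask = pages[[7]] > 0.5 / sc,
                      acquisition = acq)
  }
  mapFiles <- setdiff(list.files(dir, pattern = "\\.csv$"), "cohort.csv")
  maps <- list()
  for (f in mapFiles) {
    mid <- sub("\\.csv$", "", f)
    cls <- sub("_b[0-9]+_map$", "", mid)
    maps[[mid]] <- readRamanMapCSV(file.path(dir, f), map_id = mid,
                                   class_name = if (cls %in%
                                                      pituitaryClasses())
                                     cls else NA_character_)
  }
  sidecar <- jsonlite::fromJSON(file.path(dir, "cohort.json"))
  new("PituitaryCohort", planes = pls, ramanMaps = maps,
      seed = as.integer(sidecar$seed), generatorTruth = list())
}

#' Raman map CSV dialect
#'
#' First row: the wavenumber axis; subsequent rows: one spectrum per
#' line-scan position.
#'
#' @param map a [RamanMap-class].
#' @param path file path.
#' @export
writeRamanMapCSV <- function(map, path) {
  utils::write.table(rbind(map@wavenumbers, map@spectra), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeRamanMapCSV
#' @param map_id,class_name identifiers for the reconstructed map.
#' @export
readRamanMapCSV <- function(path, map_id = basename(path),
                            class_name = NA_character_) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  new("RamanMap", mapId = map_id, className = class_name,
      wavenumbers = m[1, ], spectra = m[-1, , drop = FALSE],
      positions = seq_len(nrow(m) - 1L))
}
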