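#' Write force curves as TSV with a JSON sidecar
#'
#' Each curve becomes \code{<cellId>_<curveId>.tsv} (columns \code{z_um},
#' \code{deflection_nm}) plus \code{<cellId>_<curveId>.json} holding the
#' probe metadata and, for synthetic curves, the ground truth.
#'
#' @param curves list of \linkS4class{ForceCurve}
#' @param dir output directory (created if needed)
#' @return invisibly, the TSV paths written
#' @export
writeForceCurves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(curves, function(cv) {
    stem <- file.path(dir, paste0(cv@cellId, "_", cv@curveId))
    utils::write.table(
      data.frame(z_um = cv@z, deflection_nm = cv@deflection),
      paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    p <- cv@probe
    jsonlite::write_json(
      list(probe = list(spring_constant_N_m = p@springConstant,
                        bead_radius_um = p@beadRadius,
                        poisson_ratio = p@poissonRatio,
                        trigger_force_nN = p@triggerForce,
                        indent_velocity_um_s = p@indentVelocity),
           cell_id = cv@cellId, curve_id = cv@curveId,
           ground_truth = cv@groundTruth),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    paste0(stem, ".tsv")
  }, "")
  invisible(paths)
}

#' Read force curves written by \code{\link{writeForceCurves}}
#'
#' @param dir directory holding TSV/JSON pairs
#' @return list of \linkS4class{ForceCurve}
#' @export
readForceCurves <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(tsvs)) stop("no .tsv curves found in ", dir)
  lapply(tsvs, function(tsv) {
    tab <- utils::read.delim(tsv)
    meta <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv),
                                simplifyVector = TRUE)
    probe <- probeSpec(
      springConstant = meta$probe$spring_constant_N_m,
      beadRadius = meta$probe$bead_radius_um,
      poissonRatio = meta$probe$poisson_ratio,
      triggerForce = meta$probe$trigger_force_nN,
      indentVelocity = meta$probe$indent_velocity_um_s)
    gt <- meta$ground_truth
    new("ForceCurve", z = tab$z_um, deflection = tab$deflection_nm,
        probe = probe, cellId = meta$cell_id, curveId = meta$curve_id,
        groundTruth = if (length(gt)) as.list(gt) else list())
  })
}

#' Write the per-cell stiffness table as CSV
#'
#' @param cells per-cell data.frame from \code{\link{analyzePopulation}}
#'   (columns cell_id, n_curves, E_kPa_mean, E_kPa_sd)
#' @param path output CSV path
#' @return invisibly, \code{path}
#' @export
writeCellTable <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cell image and mask as TIFF
#'
#' The intensity image is written as 16-bit grayscale and the mask as
#' 8-bit 0/255, the conventional exchange format for fluorescence
#' micrographs and segmentations.
#'
#' @param img list with \code{image} and \code{mask} (from
#'   \code{\link{simulateCellImage}})
#' @param prefix path prefix; writes \code{<prefix>_image.tif} and
#'   \code{<prefix>_mask.tif}
#' @return invisibly, the two paths
#' @export
writeCellImage <- function(img, prefix) {
  pi_ <- paste0(prefix, "_image.tif")
  pm <- paste0(prefix, "_mask.tif")
  tiff::writeTIFF(img$image / 65535, pi_, bits.per.sample = 16L)
  tiff::writeTIFF((img$mask != 0) * 1, pm, bits.per.sample = 8L)
  invisible(c(pi_, pm))
}

#' Read an image/mask TIFF pair written by \code{\link{writeCellImage}}
#'
#' @param prefix the path prefix used at write time
#' @return list with \code{image} (16-bit scale) and \code{mask} (0/1)
#' @export
readCellImage <- function(prefix) {
  img <- tiff::readTIFF(paste0(prefix, "_image.tif")) * 65535
  mask <- (tiff::readTIFF(paste0(prefix, "_mask.tif")) > 0.5) * 1
  list(image = img, mask = mask)
}
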