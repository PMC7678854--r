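#' Read and write 3D stacks as multi-page 32-bit TIFF
#'
#' Stacks are written as one 32-bit float page per z-plane. TIFF float
#' samples are stored normalized to [0, 1]; the normalization scale and the
#' voxel pitch (OME-style `PhysicalSize` fields) are recorded in a JSON
#' sidecar (`<path>.meta.json`) so that [readImageStack()] restores the
#' original intensities and pitch. Without a sidecar, reading falls back to
#' scale 1 and the default pitch.
#'
#' @param stack an [ImageStack3D-class].
#' @param path output/input TIFF path.
#' @return `writeImageStack` returns `path` invisibly; `readImageStack` an
#'   [ImageStack3D-class].
#' @export
writeImageStack <- function(stack, path) {
  stopIfNot3D(stack)
  scale <- max(stack@voxels)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(stack@voxels)[3]), function(j)
    stack@voxels[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  writeSidecar(path, list(
    PhysicalSizeX = stack@pitch[1], PhysicalSizeY = stack@pitch[2],
    PhysicalSizeZ = stack@pitch[3], PhysicalSizeUnit = "um",
    scale = scale, offset = 0))
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- readSidecar(path)
  vox <- simplify2array(pages)
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  vox <- vox * meta$scale + meta$offset
  vox[vox < 0] <- 0
  imageStack3D(vox, meta$pitch)
}

sidecarPath <- function(path) paste0(path, ".meta.json")

writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
}

readSidecar <- function(path) {
  meta <- list(scale = 1, offset = 0, pitch = c(0.1, 0.1, 0.2),
               unit = NULL)
  sp <- sidecarPath(path)
  if (file.exists(sp)) {
    parsed <- tryCatch(jsonlite::fromJSON(sp), error = function(e) NULL)
    if (!is.null(parsed)) {
      meta$scale <- parsed$scale %||% 1
      meta$offset <- parsed$offset %||% 0
      px <- c(parsed$PhysicalSizeX %||% 0.1, parsed$PhysicalSizeY %||% 0.1,
              parsed$PhysicalSizeZ %||% 0.2)
      meta$pitch <- as.numeric(px)
      meta$unit <- parsed$unit
    }
  }
  meta
}

#' Read and write phase images as 32-bit TIFF
#'
#' Single-page float TIFF in radians; phase maps can be negative, so both
#' an offset and a scale are recorded in the JSON sidecar alongside the
#' pixel pitch.
#'
#' @param img a [PhaseImage-class].
#' @param path file path.
#' @return `writePhaseImage` returns `path` invisibly; `readPhaseImage` a
#'   [PhaseImage-class].
#' @export
writePhaseImage <- function(img, path) {
  stopifnot(is(img, "PhaseImage"))
  lo <- min(img@phase); hi <- max(img@phase)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img@phase - lo) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  writeSidecar(path, list(
    PhysicalSizeX = img@pixelPitch, PhysicalSizeY = img@pixelPitch,
    PhysicalSizeUnit = "um", unit = "radian", offset = lo, scale = scale))
  invisible(path)
}

#' @rdname writePhaseImage
#' @export
readPhaseImage <- function(path) {
  if (!file.exists(path))
    stop("phase image not found: ", path, call. = FALSE)
  page <- tiff::readTIFF(path)
  meta <- readSidecar(path)
  phaseImage(page * meta$scale + meta$offset, meta$pitch[1])
}

#' Read a YAML or JSON configuration file
#'
#' @param path file path; format chosen by extension (`.json` vs YAML
#'   otherwise; the YAML parser accepts JSON documents too).
#' @return named list.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Write a per-cell record table as CSV
#'
#' @param records data.frame from [analyzeCells()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
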