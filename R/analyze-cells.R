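#' Analysis configuration for the cell pipeline
#'
#' Thresholds and geometric parameters of [analyzeCells()]. Phase
#' thresholds are free parameters of the assay (cytosol and droplet phase
#' levels depend on specimen and wavelength); the defaults match the
#' package's phantom generator.
#'
#' @param cellThreshold cell segmentation phase threshold, rad.
#' @param ldThreshold droplet segmentation phase threshold, rad (higher
#'   than `cellThreshold`: droplets are phase-denser than cytosol).
#' @param minArea minimum cell area, um^2.
#' @param ldMinArea minimum droplet area, um^2.
#' @param shellMargin droplet-surface shell half-thickness for localization
#'   calls, um.
#' @param localizedFractionThreshold shell-flux fraction above which a cell
#'   is localized.
#' @param contactDistance contact radius for surface coverage, um
#'   (`NULL`: one voxel diagonal).
#' @param coverageThresholdFactor a voxel counts as fluorescent for
#'   coverage when it exceeds background + factor x (cell max -
#'   background).
#' @param dryDensity a [dryDensityParams()] list.
#' @return named list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(cellThreshold = 0.5, ldThreshold = 1.45,
                           minArea = 3, ldMinArea = 0.15,
                           shellMargin = 0.3,
                           localizedFractionThreshold = 0.5,
                           contactDistance = NULL,
                           coverageThresholdFactor = 0.2,
                           dryDensity = dryDensityParams()) {
  structure(as.list(environment()), class = "AnalysisConfig")
}

#' Per-cell QPI + fluorescence analysis
#'
#' Composes the analysis chain on a registered phase image / fluorescence
#' stack pair: phase-threshold segmentation of cells (border-touching cells
#' excluded), droplet segmentation inside each cell at the higher
#' threshold, dry-mass surface density from the mean phase, background-
#' subtracted expression, LD-localization classification and percent
#' droplet-surface coverage.
#'
#' @param phase a [PhaseImage-class].
#' @param fluor an [ImageStack3D-class] registered to the same lateral
#'   grid (same dimensions and pitch).
#' @param config an [analysisConfig()] list.
#' @return data.frame with one row per analyzed cell: `cell_id`, `x_um`,
#'   `y_um` (centroid), `area_um2`, `mean_phase_rad`,
#'   `dry_density_pg_um2`, `erg6_expr`, `localization`, `ld_diam_um`,
#'   `coverage_pct` (NA without a droplet).
#' @export
analyzeCells <- function(phase, fluor, config = analysisConfig()) {
  stopifnot(is(phase, "PhaseImage"), inherits(config, "AnalysisConfig"))
  stopIfNot3D(fluor)
  dimsF <- dim(fluor@voxels)
  if (!all(dim(phase@phase) == dimsF[1:2]))
    stop("phase image (", paste(dim(phase@phase), collapse = "x"),
         ") and fluorescence stack (", paste(dimsF[1:2], collapse = "x"),
         " laterally) are not registered", call. = FALSE)
  if (abs(phase@pixelPitch - fluor@pitch[1]) > 1e-6 ||
      abs(phase@pixelPitch - fluor@pitch[2]) > 1e-6)
    stop("phase pixel pitch and fluorescence lateral pitch differ",
         call. = FALSE)
  cells <- segmentByPhase(phase, config$cellThreshold, config$minArea)
  cells <- Filter(function(m) !touchesBorder(m), cells)
  empty <- data.frame(cell_id = integer(), x_um = numeric(),
                      y_um = numeric(), area_um2 = numeric(),
                      mean_phase_rad = numeric(),
                      dry_density_pg_um2 = numeric(),
                      erg6_expr = numeric(), localization = character(),
                      ld_diam_um = numeric(), coverage_pct = numeric())
  if (!length(cells)) return(empty)
  anyCell <- Reduce(`|`, cells)
  bgMask <- !anyCell
  lds <- segmentByPhase(phase, config$ldThreshold, config$ldMinArea)
  zs <- centeredCoords(dimsF[3], fluor@pitch[3])
  rows <- lapply(seq_along(cells), function(i) {
    m <- cells[[i]]
    meanPhase <- mean(phase@phase[m])
    expr <- expressionLevel(fluor, m, bgMask)
    # droplet: the largest high-phase region lying mostly inside the cell
    ldMask <- NULL
    for (cand in lds) {
      if (sum(cand & m) / sum(cand) >= 0.5) { ldMask <- cand; break }
    }
    ldDiam <- NA_real_; coverage <- NA_real_; ldCenter <- NULL
    if (!is.null(ldMask)) {
      ldDiam <- 2 * sqrt(attr(ldMask, "area_um2") / pi)
      cen <- attr(ldMask, "centroid_um")
      # droplet z: plane of maximal in-footprint fluorescence
      inMask <- which(array(ldMask, dimsF))
      perPlane <- vapply(seq_len(dimsF[3]), function(j)
        sum(fluor@voxels[, , j][ldMask]), numeric(1))
      ldCenter <- c(cen, zs[which.max(perPlane)])
      bgLevel <- stats::median(fluor@voxels[array(bgMask, dimsF)])
      cellMax <- max(fluor@voxels[array(m, dimsF)])
      thr <- bgLevel + config$coverageThresholdFactor * (cellMax - bgLevel)
      coverage <- tryCatch(
        ldSurfaceCoverage(fluor, ldCenter, ldDiam,
                          contactDistance = config$contactDistance,
                          intensityThreshold = thr),
        error = function(e) NA_real_)
    }
    bgVox <- fluor@voxels[array(bgMask, dimsF)]
    loc <- classifyLocalization(
      fluor, ldCenter, ldDiam, shellMargin = config$shellMargin,
      localizedFractionThreshold = config$localizedFractionThreshold,
      background = stats::median(bgVox) + 2 * stats::sd(bgVox),
      cellMask = m)
    cen <- attr(m, "centroid_um")
    data.frame(cell_id = i, x_um = cen[1], y_um = cen[2],
               area_um2 = attr(m, "area_um2"),
               mean_phase_rad = meanPhase,
               dry_density_pg_um2 = dryDensity(meanPhase,
                                               config$dryDensity),
               erg6_expr = as.numeric(expr), localization = loc,
               ld_diam_um = ldDiam, coverage_pct = coverage)
  })
  do.call(rbind, rows)
}
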