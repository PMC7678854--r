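#' Default parameters of the cell-scene generator
#'
#' The generator emulates sedimented oleaginous-yeast cells: ellipsoids with
#' an in-plane major axis drawn from Normal(5.3, 0.4) um, an in-plane
#' aspect ratio drawn uniformly from `aspectRange`, and the out-of-plane
#' semi-axis equal to the in-plane minor semi-axis (prolate spheroid lying
#' flat). Cytosol phase is proportional to the optical chord length through
#' the cell; lipid droplets add excess phase over their footprint.
#' Fluorophore truth per cell: an expression level (Normal, shifted up by
#' `localizedEffectSize` standard deviations for LD-localized cells), a
#' localization mode, and - for localized cells - a set surface-coverage
#' fraction drawn from `coverageRange`.
#'
#' The cytosol dry density is modelled as constant across cells: each
#' cell's phase-per-chord scale is `peakCytosolPhase / (2 b)` (b the
#' out-of-plane semi-axis), so every cell peaks at the same cytosol phase
#' regardless of its size - which is what makes a single global phase
#' threshold meaningful for segmenting a population.
#'
#' @param fieldSize lateral field (x, y), um.
#' @param majorMean,majorSd major-axis distribution, um.
#' @param aspectRange in-plane aspect-ratio range (major/minor).
#' @param peakCytosolPhase peak cytosol phase of every cell, rad.
#' @param ldCountRange inclusive range of droplets per cell.
#' @param ldDiameterRange droplet diameter range, um.
#' @param ldPhaseScale droplet excess phase per um of chord, rad/um.
#' @param expressionMean,expressionSd expression-level distribution
#'   (arbitrary fluorescence units).
#' @param localizedFraction probability that a cell is LD-localized.
#' @param localizedEffectSize expression shift of localized cells, in SD
#'   units.
#' @param coverageRange coverage-fraction range for localized cells.
#' @param placementMargin clearance from the field border beyond the cell's
#'   bounding radius, um.
#' @param maxAttempts rejection-sampling budget for non-overlapping
#'   placement.
#' @return named list of parameters.
#' @export
cellSceneParams <- function(fieldSize = c(60, 60),
                            majorMean = 5.3, majorSd = 0.4,
                            aspectRange = c(1.2, 1.6),
                            peakCytosolPhase = 1.3,
                            ldCountRange = c(0, 2),
                            ldDiameterRange = c(1.0, 1.6),
                            ldPhaseScale = 0.6,
                            expressionMean = 120, expressionSd = 30,
                            localizedFraction = 0.5,
                            localizedEffectSize = 1,
                            coverageRange = c(0.2, 0.8),
                            placementMargin = 1,
                            maxAttempts = 1e4) {
  as.list(environment())
}

#' Generate a ground-truthed cell scene
#'
#' Places `nCells` non-overlapping ellipsoidal cells in the field by
#' rejection sampling and draws the per-cell droplet geometry and
#' fluorophore truth. The seed fixes all randomness: the same seed always
#' yields an identical scene.
#'
#' @param nCells number of cells (>= 0).
#' @param params a [cellSceneParams()] list.
#' @param seed integer seed.
#' @return a [CellScene-class].
#' @examples
#' sc <- generateCellScene(3, seed = 1)
#' @export
generateCellScene <- function(nCells, params = cellSceneParams(), seed = 1) {
  stopifnot(nCells >= 0)
  withSeed(seed, {
    cells <- data.frame(x = numeric(), y = numeric(), major = numeric(),
                        aspect = numeric(), orientation = numeric(),
                        cytosolPhaseScale = numeric())
    attempts <- 0L
    while (nrow(cells) < nCells) {
      attempts <- attempts + 1L
      if (attempts > params$maxAttempts)
        stop("could not place ", nCells, " non-overlapping cells in a ",
             paste(params$fieldSize, collapse = " x "),
             " um field after ", params$maxAttempts,
             " attempts; enlarge the field", call. = FALSE)
      major <- max(1, stats::rnorm(1, params$majorMean, params$majorSd))
      R <- major / 2
      lim <- params$fieldSize / 2 - R - params$placementMargin
      if (any(lim <= 0)) next
      x <- stats::runif(1, -lim[1], lim[1])
      y <- stats::runif(1, -lim[2], lim[2])
      if (nrow(cells)) {
        dd <- sqrt((cells$x - x)^2 + (cells$y - y)^2)
        if (any(dd < cells$major / 2 + R + 0.5)) next
      }
      aspect <- stats::runif(1, params$aspectRange[1],
                             params$aspectRange[2])
      # constant volumetric density: scale so the peak phase (through the
      # thickest chord, 2b) is the same for every cell
      cells <- rbind(cells, data.frame(
        x = x, y = y, major = major, aspect = aspect,
        orientation = stats::runif(1, 0, pi),
        cytosolPhaseScale = params$peakCytosolPhase / (major / aspect)))
    }
    lds <- data.frame(cell = integer(), dx = numeric(), dy = numeric(),
                      diameter = numeric(), phaseScale = numeric())
    nLds <- if (nCells)
      sample(params$ldCountRange[1]:params$ldCountRange[2], nCells,
             replace = TRUE) else integer()
    for (i in seq_len(nCells)) {
      a <- cells$major[i] / 2
      b <- a / cells$aspect[i]
      for (j in seq_len(nLds[i])) {
        dmax <- min(diff(range(params$ldDiameterRange)) + # guard tiny cells
                    params$ldDiameterRange[1], 1.6 * b)
        dia <- stats::runif(1, min(params$ldDiameterRange[1], dmax), dmax)
        r <- dia / 2
        # offset in the cell frame, keeping the droplet inside the ellipsoid
        repeat {
          fx <- stats::runif(1, -1, 1); fy <- stats::runif(1, -1, 1)
          if (fx^2 + fy^2 <= 0.25) break
        }
        dxc <- fx * (a - r - 0.1)
        dyc <- fy * (b - r - 0.1)
        th <- cells$orientation[i]
        lds <- rbind(lds, data.frame(
          cell = i,
          dx = dxc * cos(th) - dyc * sin(th),
          dy = dxc * sin(th) + dyc * cos(th),
          diameter = dia, phaseScale = params$ldPhaseScale))
      }
    }
    hasLd <- seq_len(nCells) %in% lds$cell
    mode <- ifelse(hasLd &
                     stats::runif(nCells) < params$localizedFraction,
                   "localized", "diffusive")
    expr <- stats::rnorm(nCells,
                         params$expressionMean + ifelse(mode == "localized",
                           params$localizedEffectSize *
                             params$expressionSd, 0),
                         params$expressionSd)
    expr <- pmax(expr, params$expressionMean / 10)
    coverage <- ifelse(mode == "localized",
                       stats::runif(nCells, params$coverageRange[1],
                                    params$coverageRange[2]), NA_real_)
    truth <- data.frame(cell = seq_len(nCells), expression = expr,
                        mode = mode, coverage = coverage,
                        dryMass = sceneDryMass(cells, lds))
    new("CellScene", cells = cells, lds = lds, truth = truth,
        fieldSize = params$fieldSize, seed = as.integer(seed),
        params = params)
  })
}

# Analytic dry mass per cell (pg): the projected-phase integral equals the
# chord scale times the ellipsoid volume, converted by the dry-density
# relation at its default wavelength and refractive increment.
sceneDryMass <- function(cells, lds) {
  if (!nrow(cells)) return(numeric())
  p <- dryDensityParams()
  factor <- p$wavelength * 1e-3 / (2 * pi * p$refractiveIncrement)
  vapply(seq_len(nrow(cells)), function(i) {
    a <- cells$major[i] / 2; b <- a / cells$aspect[i]; cc <- b
    v <- 4 / 3 * pi * a * b * cc
    m <- factor * cells$cytosolPhaseScale[i] * v
    mine <- lds[lds$cell == i, , drop = FALSE]
    if (nrow(mine))
      m <- m + sum(factor * mine$phaseScale * 4 / 3 * pi *
                     (mine$diameter / 2)^3)
    m
  }, numeric(1))
}

setMethod("show", "CellScene", function(object) {
  cat("CellScene:", nrow(object@cells), "cell(s),", nrow(object@lds),
      "lipid droplet(s) in a", paste(object@fieldSize, collapse = " x "),
      "um field (seed", object@seed, ")\n")
  if (nrow(object@truth)) {
    tab <- table(object@truth$mode)
    cat("  modes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

#' Project a cell scene to a quantitative-phase image
#'
#' The optical phase of each pixel is the chord length of the ray through
#' the cell's ellipsoid times the cytosol phase scale, plus the droplets'
#' excess chord phase over their footprints; the background is exactly
#' zero.
#'
#' @param scene a [CellScene-class].
#' @param pixelPitch pixel pitch, um (default 0.1).
#' @param noiseSd standard deviation of additive Gaussian phase noise, rad
#'   (default 0: noiseless). The phase signal-to-noise ratio is
#'   `peakCytosolPhase / noiseSd`.
#' @param noiseSeed seed for the phase noise (default the scene seed).
#' @return a [PhaseImage-class].
#' @export
sceneToPhase <- function(scene, pixelPitch = 0.1, noiseSd = 0,
                         noiseSeed = NULL) {
  stopifnot(is(scene, "CellScene"))
  dims <- round(scene@fieldSize / pixelPitch)
  img <- matrix(0, dims[1], dims[2])
  xs <- centeredCoords(dims[1], pixelPitch)
  ys <- centeredCoords(dims[2], pixelPitch)
  for (i in seq_len(nrow(scene@cells))) {
    cl <- scene@cells[i, ]
    a <- cl$major / 2; b <- a / cl$aspect; cc <- b
    R <- a + pixelPitch
    ix <- which(abs(xs - cl$x) <= R)
    iy <- which(abs(ys - cl$y) <= R)
    if (!length(ix) || !length(iy)) next
    dx <- xs[ix] - cl$x; dy <- ys[iy] - cl$y
    co <- cos(cl$orientation); si <- sin(cl$orientation)
    u <- outer(dx, dy * 0, "+") * co + outer(dx * 0, dy, "+") * si
    v <- -outer(dx, dy * 0, "+") * si + outer(dx * 0, dy, "+") * co
    arg <- 1 - (u / a)^2 - (v / b)^2
    chord <- 2 * cc * sqrt(pmax(arg, 0))
    img[ix, iy] <- img[ix, iy] + cl$cytosolPhaseScale * chord
  }
  for (j in seq_len(nrow(scene@lds))) {
    ld <- scene@lds[j, ]
    cl <- scene@cells[ld$cell, ]
    cx <- cl$x + ld$dx; cy <- cl$y + ld$dy
    r <- ld$diameter / 2
    ix <- which(abs(xs - cx) <= r + pixelPitch)
    iy <- which(abs(ys - cy) <= r + pixelPitch)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+")
    chord <- 2 * sqrt(pmax(r^2 - d2, 0))
    img[ix, iy] <- img[ix, iy] + ld$phaseScale * chord
  }
  if (noiseSd > 0) {
    if (is.null(noiseSeed)) noiseSeed <- scene@seed + 2L
    img <- img + withSeed(noiseSeed,
                          matrix(stats::rnorm(length(img), 0, noiseSd),
                                 nrow(img), ncol(img)))
  }
  phaseImage(img, pixelPitch)
}

#' Render the fluorophore distribution of a scene
#'
#' Builds the ground-truth fluorophore density - uniform in the cell volume
#' for diffusive cells, concentrated on a spherical cap of the first
#' droplet's surface (covering the truth coverage fraction, around a
#' seeded random axis) for localized cells - with total flux proportional
#' to the truth expression level, blurs it with the system PSF, adds the
#' background, and (optionally) applies Poisson noise.
#'
#' @param scene a [CellScene-class].
#' @param psf system PSF, an [ImageStack3D-class]; its pitch sets the stack
#'   pitch.
#' @param zExtent axial extent of the stack, um (default 8).
#' @param background expected photons per voxel (default 5).
#' @param fluxPerExpression expected photons per voxel of the cell's
#'   extruded footprint column, per expression unit (default 0.25). With
#'   this scaling a cell's background-subtracted mean intensity over its
#'   2D footprint is approximately `expression * fluxPerExpression`
#'   regardless of cell size, matching how expression is quantified.
#' @param shellThickness half-thickness of the droplet-surface shell for
#'   localized flux, um (default 0.15).
#' @param noiseSeed seed for Poisson noise, or `NULL` for the noiseless
#'   expectation.
#' @return an [ImageStack3D-class]; attribute `truthDensity` holds the
#'   unblurred truth array.
#' @export
sceneToFluor <- function(scene, psf, zExtent = 8, background = 5,
                         fluxPerExpression = 0.25, shellThickness = 0.15,
                         noiseSeed = NULL) {
  stopifnot(is(scene, "CellScene"))
  stopIfNot3D(psf)
  pitch <- psf@pitch
  dims <- c(round(scene@fieldSize / pitch[1:2]), round(zExtent / pitch[3]))
  truth <- array(0, dims)
  xs <- centeredCoords(dims[1], pitch[1])
  ys <- centeredCoords(dims[2], pitch[2])
  zs <- centeredCoords(dims[3], pitch[3])
  capAxes <- withSeed(scene@seed + 1L, {
    n <- max(1L, nrow(scene@cells))
    phi <- stats::runif(n, 0, 2 * pi)
    cth <- stats::runif(n, -1, 1)
    cbind(sqrt(1 - cth^2) * cos(phi), sqrt(1 - cth^2) * sin(phi), cth)
  })
  voxelVol <- prod(pitch)
  for (i in seq_len(nrow(scene@cells))) {
    cl <- scene@cells[i, ]
    tr <- scene@truth[i, ]
    aSemi <- cl$major / 2
    bSemi <- aSemi / cl$aspect
    # total flux scaled to the cell's footprint column so that the mean
    # in-footprint intensity tracks the expression level itself
    flux <- tr$expression * fluxPerExpression *
      pi * aSemi * bSemi * zExtent / voxelVol
    mine <- scene@lds[scene@lds$cell == i, , drop = FALSE]
    if (tr$mode == "localized" && nrow(mine)) {
      ld <- mine[1, ]
      cx <- cl$x + ld$dx; cy <- cl$y + ld$dy
      r <- ld$diameter / 2
      ix <- which(abs(xs - cx) <= r + 3 * shellThickness)
      iy <- which(abs(ys - cy) <= r + 3 * shellThickness)
      iz <- which(abs(zs) <= r + 3 * shellThickness)
      ax <- capAxes[i, ]
      cosCap <- 1 - 2 * tr$coverage   # cap area fraction -> polar angle
      sel <- array(FALSE, dims)
      for (kz in iz) {
        d2 <- outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+") + zs[kz]^2
        dist <- sqrt(d2)
        shell <- abs(dist - r) <= shellThickness
        # cap membership: angle from the cap axis
        ca <- (outer(xs[ix] - cx, ys[iy] * 0, "+") * ax[1] +
               outer(xs[ix] * 0, ys[iy] - cy, "+") * ax[2] +
               zs[kz] * ax[3]) / pmax(dist, 1e-9)
        sel[ix, iy, kz] <- shell & ca >= cosCap
      }
      nsel <- sum(sel)
      if (nsel) truth[sel] <- truth[sel] + flux / nsel
    } else {
      a <- cl$major / 2; b <- a / cl$aspect; cc <- b
      ix <- which(abs(xs - cl$x) <= a + pitch[1])
      iy <- which(abs(ys - cl$y) <= a + pitch[2])
      iz <- which(abs(zs) <= cc + pitch[3])
      co <- cos(cl$orientation); si <- sin(cl$orientation)
      dx <- xs[ix] - cl$x; dy <- ys[iy] - cl$y
      u <- outer(dx, dy * 0, "+") * co + outer(dx * 0, dy, "+") * si
      v <- -outer(dx, dy * 0, "+") * si + outer(dx * 0, dy, "+") * co
      lat <- (u / a)^2 + (v / b)^2
      sel <- array(FALSE, dims)
      for (kz in iz)
        sel[ix, iy, kz] <- lat + (zs[kz] / cc)^2 <= 1
      nsel <- sum(sel)
      if (nsel) truth[sel] <- truth[sel] + flux / nsel
    }
  }
  expected <- linearConvolve3(truth, psf@voxels) + background
  expected[expected < 0] <- 0
  vox <- if (is.null(noiseSeed)) expected else
    withSeed(noiseSeed,
             array(stats::rpois(length(expected), expected), dim(expected)))
  out <- imageStack3D(vox, pitch)
  attr(out, "truthDensity") <- truth
  out
}

#' Random bead phantom
#'
#' Beads uniformly placed in the inner 80 % of the volume, for PSF and
#' resolution work (defaults: 0.5 um beads, as used for axial-resolution
#' metrology).
#'
#' @param nBeads number of beads.
#' @param extent volume extent (x, y, z), um.
#' @param diameter bead diameter, um (default 0.5).
#' @param brightness expected photons per bead (default 2e4).
#' @param background expected photons per voxel (default 5).
#' @param seed integer seed.
#' @return a [BeadPhantom-class].
#' @export
randomBeadPhantom <- function(nBeads, extent, diameter = 0.5,
                              brightness = 2e4, background = 5, seed = 1) {
  withSeed(seed, {
    lim <- extent * 0.4
    beadPhantom(data.frame(
      x = stats::runif(nBeads, -lim[1], lim[1]),
      y = stats::runif(nBeads, -lim[2], lim[2]),
      z = stats::runif(nBeads, -lim[3], lim[3]),
      diameter = diameter, brightness = brightness), background)
  })
}
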