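#' Dry-density parameters
#'
#' Wavelength and refractive increment used to convert mean optical phase to
#' dry-mass surface density. The refractive increment dn/dc ~ 1.85e-4
#' m^3 kg^-1 is the standard value for cellular biomolecular mass.
#'
#' @param wavelength wavelength, um (default 0.5).
#' @param refractiveIncrement dn/dc in m^3 kg^-1 (default 1.85e-4).
#' @return a parameter list of class `DryDensityParams`.
#' @export
dryDensityParams <- function(wavelength = 0.5,
                             refractiveIncrement = 1.85e-4) {
  if (wavelength <= 0 || refractiveIncrement <= 0)
    stop("wavelength and refractiveIncrement must be positive",
         call. = FALSE)
  structure(list(wavelength = wavelength,
                 refractiveIncrement = refractiveIncrement),
            class = "DryDensityParams")
}

#' Dry-mass surface density from mean phase
#'
#' \deqn{\rho = \frac{\lambda}{2\pi\, dn/dc}\,\langle\Phi\rangle}
#'
#' With the wavelength in um and dn/dc in m^3 kg^-1 the result is returned
#' in pg um^-2; the conversion is
#' \eqn{1\ \mathrm{kg\,m^{-2}} = 1000\ \mathrm{pg\,\mu m^{-2}}}, so
#' \eqn{\rho\ [\mathrm{pg\,\mu m^{-2}}] =
#'  10^{-3}\lambda_{\mu m}\,\langle\Phi\rangle/(2\pi\,dn/dc)}.
#' The relation is exactly linear in the phase.
#'
#' @param meanPhase mean optical phase, radians (vectorised).
#' @param params a [dryDensityParams()] list.
#' @return dry density in pg um^-2.
#' @examples
#' dryDensity(1, dryDensityParams())   # ~0.430 pg/um^2
#' @export
dryDensity <- function(meanPhase, params = dryDensityParams()) {
  stopifnot(inherits(params, "DryDensityParams"))
  lambda_m <- params$wavelength * 1e-6
  rho_kg_m2 <- lambda_m / (2 * pi * params$refractiveIncrement) * meanPhase
  rho_kg_m2 * 1e3   # kg m^-2 -> pg um^-2
}

#' Background-subtracted expression level
#'
#' Mean fluorescence intensity over the cell's voxels minus the mean over an
#' extracellular background region. The result may be negative (cells dimmer
#' than background are flagged, not clipped). 2D masks are extruded across
#' all z-planes.
#'
#' @param stack fluorescence stack, an [ImageStack3D-class].
#' @param cellMask logical matrix (2D, extruded over z) or 3D array
#'   selecting the cell's voxels.
#' @param backgroundRegion logical matrix or 3D array selecting background
#'   voxels.
#' @return numeric(1); attribute `negative` is TRUE when below zero.
#' @export
expressionLevel <- function(stack, cellMask, backgroundRegion) {
  stopIfNot3D(stack)
  cellVox <- maskToVoxels(cellMask, dim(stack@voxels))
  bgVox <- maskToVoxels(backgroundRegion, dim(stack@voxels))
  if (!any(cellVox)) stop("empty cell region", call. = FALSE)
  if (!any(bgVox)) stop("empty background region", call. = FALSE)
  val <- mean(stack@voxels[cellVox]) - mean(stack@voxels[bgVox])
  structure(val, negative = val < 0)
}

# Accept a 2D mask (extruded along z) or a full 3D mask.
maskToVoxels <- function(mask, dims) {
  if (is.matrix(mask)) {
    if (!all(dim(mask) == dims[1:2]))
      stop("2D mask does not match the stack's lateral dimensions",
           call. = FALSE)
    array(mask, dims)
  } else {
    if (!all(dim(mask) == dims))
      stop("3D mask does not match the stack dimensions", call. = FALSE)
    mask
  }
}

# Voxel-centre distances from a 3D point, as an array matching the stack.
voxelDistances <- function(dims, pitch, center) {
  xs <- centeredCoords(dims[1], pitch[1]) - center[1]
  ys <- centeredCoords(dims[2], pitch[2]) - center[2]
  zs <- centeredCoords(dims[3], pitch[3]) - center[3]
  sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
}

#' Classify a cell's fluorophore distribution as LD-localized or diffusive
#'
#' A cell is called "localized" when the fraction of its above-background
#' fluorescence flux lying within the spherical shell around the lipid
#' droplet surface (radius r_LD +- `shellMargin`) exceeds
#' `localizedFractionThreshold`. Without a droplet the call is "diffusive"
#' by definition.
#'
#' @param fluor fluorescence stack, an [ImageStack3D-class].
#' @param ldCenter droplet centre (x, y, z) in um, or `NULL` for no droplet.
#' @param ldDiameter droplet diameter, um.
#' @param shellMargin half-thickness of the surface shell, um (default 0.3).
#' @param localizedFractionThreshold flux fraction above which the cell is
#'   localized (default 0.5).
#' @param background intensity attributed to background, subtracted (and
#'   floored at zero) before computing flux; default the stack's median.
#' @param cellMask optional mask restricting the flux bookkeeping to one
#'   cell's voxels.
#' @return "localized" or "diffusive".
#' @export
classifyLocalization <- function(fluor, ldCenter, ldDiameter,
                                 shellMargin = 0.3,
                                 localizedFractionThreshold = 0.5,
                                 background = NULL, cellMask = NULL) {
  stopIfNot3D(fluor)
  if (is.null(ldCenter)) return("diffusive")
  if (ldDiameter <= 0) stop("ldDiameter must be positive", call. = FALSE)
  if (is.null(background)) background <- stats::median(fluor@voxels)
  flux <- pmax(fluor@voxels - background, 0)
  if (!is.null(cellMask))
    flux <- flux * maskToVoxels(cellMask, dim(fluor@voxels))
  tot <- sum(flux)
  if (tot <= 0) return("diffusive")
  dist <- voxelDistances(dim(fluor@voxels), fluor@pitch, ldCenter)
  shell <- abs(dist - ldDiameter / 2) <= shellMargin
  frac <- sum(flux[shell]) / tot
  if (frac > localizedFractionThreshold) "localized" else "diffusive"
}

#' Percent of the LD surface in contact with fluorescence
#'
#' The droplet surface is discretized into patches: the surface voxels of
#' the rasterized sphere of the given diameter (sphere voxels with at least
#' one 6-neighbour outside the sphere). A patch counts as covered when at
#' least one supra-threshold fluorescence voxel lies within
#' `contactDistance` of its centre. Coverage is
#' 100 x covered patches / total patches.
#'
#' @param fluor fluorescence stack, an [ImageStack3D-class].
#' @param ldCenter droplet centre (x, y, z), um.
#' @param ldDiameter droplet diameter, um.
#' @param contactDistance contact radius, um; must be at least the largest
#'   voxel pitch (default: one voxel diagonal).
#' @param intensityThreshold fluorescence level above which a voxel counts
#'   as fluorescent.
#' @return coverage percentage in [0, 100].
#' @export
ldSurfaceCoverage <- function(fluor, ldCenter, ldDiameter,
                              contactDistance = NULL, intensityThreshold) {
  stopIfNot3D(fluor)
  if (ldDiameter <= 0) stop("ldDiameter must be positive", call. = FALSE)
  dims <- dim(fluor@voxels)
  pitch <- fluor@pitch
  if (is.null(contactDistance)) contactDistance <- sqrt(sum(pitch^2))
  if (contactDistance < max(pitch))
    stop("contactDistance must be at least the largest voxel pitch (",
         max(pitch), " um)", call. = FALSE)
  halfExtent <- dims * pitch / 2
  if (any(abs(ldCenter) + ldDiameter / 2 > halfExtent))
    stop("droplet sphere extends outside the volume", call. = FALSE)
  dist <- voxelDistances(dims, pitch, ldCenter)
  sphere <- dist <= ldDiameter / 2
  if (!any(sphere)) {
    # droplet smaller than a voxel: treat the nearest voxel as the surface
    sphere <- array(FALSE, dims)
    cvox <- pmin(pmax(round(ldCenter / pitch + (floor(dims / 2) + 1)), 1),
                 dims)
    sphere[cvox[1], cvox[2], cvox[3]] <- TRUE
  }
  surface <- sphere & !erode6(sphere)
  surfIdx <- which(surface, arr.ind = TRUE)
  supra <- fluor@voxels > intensityThreshold
  if (!any(supra)) return(0)
  # neighbourhood offsets within the physical contact distance
  rad <- ceiling(contactDistance / pitch)
  offs <- as.matrix(expand.grid(x = -rad[1]:rad[1], y = -rad[2]:rad[2],
                                z = -rad[3]:rad[3]))
  physd <- sqrt((offs[, 1] * pitch[1])^2 + (offs[, 2] * pitch[2])^2 +
                (offs[, 3] * pitch[3])^2)
  offs <- offs[physd <= contactDistance, , drop = FALSE]
  covered <- 0L
  for (i in seq_len(nrow(surfIdx))) {
    nb <- sweep(offs, 2, surfIdx[i, ], "+")
    okn <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
           nb[, 2] >= 1 & nb[, 2] <= dims[2] &
           nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (any(supra[nb[okn, , drop = FALSE]])) covered <- covered + 1L
  }
  100 * covered / nrow(surfIdx)
}

# 6-connected erosion of a logical 3D array (FALSE outside).
erode6 <- function(a) {
  d <- dim(a)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len); dst <- src
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- (1 + by):n; src[[ax]] <- 1:(n - by) }
    else { dst[[ax]] <- 1:(n + by); src[[ax]] <- (1 - by):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  a & shift(a, 1, 1) & shift(a, 1, -1) & shift(a, 2, 1) & shift(a, 2, -1) &
    shift(a, 3, 1) & shift(a, 3, -1)
}
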