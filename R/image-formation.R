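#' Detection-parameter constructor
#'
#' @param numericalAperture detection NA (default 0.7).
#' @param emissionWavelength emission wavelength, um (default 0.525).
#' @param mediumIndex sample-medium index (default 1.33).
#' @return a [DetectionParams-class].
#' @export
detectionParams <- function(numericalAperture = 0.7,
                            emissionWavelength = 0.525,
                            mediumIndex = 1.33) {
  new("DetectionParams", numericalAperture = numericalAperture,
      emissionWavelength = emissionWavelength, mediumIndex = mediumIndex)
}

# Scalar paraxial widefield PSF on an (r, z) polar grid.
#
# h(r, z) = | 2 * int_0^1 J0(v rho) exp(i u rho^2 / 2) rho d rho |^2
# with optical coordinates v = k NA r and u = k NA^2 z / n. The radial
# integral is evaluated by Gauss-Legendre quadrature (128 nodes), which is
# plenty for the mildly oscillatory integrand at NA <= ~0.9.
scalarPSFRadial <- function(rr, zz, na, lambda, n) {
  k <- 2 * pi / lambda
  nodes <- 128L
  # Gauss-Legendre on [0, 1]
  gl <- legendreNodes(nodes)
  rho <- (gl$x + 1) / 2
  wgt <- gl$w / 2
  v <- k * na * rr                      # length nr
  u <- k * na^2 * zz / n                # length nz
  J <- besselJ(outer(v, rho), 0)        # nr x nodes
  out <- matrix(0, length(rr), length(zz))
  for (j in seq_along(u)) {
    defoc <- exp(1i * u[j] * rho^2 / 2) * rho * wgt
    amp <- 2 * (J %*% defoc)
    out[, j] <- Mod(amp)^2
  }
  out
}

# Legendre-Gauss nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
legendreNodes <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Synthetic widefield detection PSF
#'
#' Scalar-diffraction (paraxial pupil-integral) widefield PSF for a circular
#' pupil of the given numerical aperture, sampled on a 3D voxel grid and
#' normalized to unit sum. The lateral profile at focus is the Airy pattern
#' `[2 J1(v)/v]^2`, giving a lateral FWHM of about `0.51 lambda / NA`.
#'
#' @param params a [DetectionParams-class].
#' @param pitch voxel pitch (x, y, z), um.
#' @param extent full grid extent (x, y, z), um; must cover at least three
#'   lateral and three axial FWHMs.
#' @return an [ImageStack3D-class] with odd dimensions and unit sum.
#' @examples
#' psf <- detectionPSF(detectionParams(), pitch = c(0.1, 0.1, 0.2),
#'                     extent = c(2, 2, 8))
#' @export
detectionPSF <- function(params, pitch = c(0.1, 0.1, 0.2),
                         extent = c(2, 2, 8)) {
  stopifnot(is(params, "DetectionParams"))
  validObject(params)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  na <- params@numericalAperture
  lambda <- params@emissionWavelength
  n <- params@mediumIndex
  fwhmLat <- 0.51 * lambda / na
  fwhmAx <- 1.77 * n * lambda / na^2
  if (extent[1] < 3 * fwhmLat || extent[2] < 3 * fwhmLat)
    stop("lateral extent must cover at least 3 lateral FWHM (",
         format(3 * fwhmLat, digits = 3), " um)", call. = FALSE)
  if (extent[3] < 3 * fwhmAx)
    stop("axial extent must cover at least 3 axial FWHM (",
         format(3 * fwhmAx, digits = 3), " um)", call. = FALSE)
  dims <- 2L * floor(extent / (2 * pitch)) + 1L  # odd, centred
  xs <- centeredCoords(dims[1], pitch[1])
  ys <- centeredCoords(dims[2], pitch[2])
  zs <- centeredCoords(dims[3], pitch[3])
  rmax <- sqrt(max(xs)^2 + max(ys)^2)
  rfine <- seq(0, rmax + max(pitch[1:2]), by = min(pitch[1:2]) / 4)
  hz <- scalarPSFRadial(rfine, zs, na, lambda, n)
  r2d <- sqrt(outer(xs^2, ys^2, "+"))
  vox <- array(0, dims)
  for (j in seq_len(dims[3])) {
    vox[, , j] <- matrix(stats::approx(rfine, hz[, j], xout = r2d,
                                       rule = 2)$y, dims[1], dims[2])
  }
  vox <- vox / sum(vox)
  imageStack3D(vox, pitch)
}

#' Illumination profile of the scanned sheet at one propagation distance
#'
#' Extracts the sheet's intensity against the detection-axis coordinate from
#' a beam map, at the requested propagation distance. Scanning the beam
#' across the field is modelled as uniform, so the profile at a given
#' propagation distance is simply the beam's transverse intensity there
#' (the scan averages over the scan axis, which the 2D beam model does not
#' carry).
#'
#' @param map a [BeamIntensityMap-class] (transverse axis = detection z).
#' @param xPosition propagation distance, um; must lie inside the map's
#'   axial range. The nearest sampled plane is used.
#' @return data.frame with columns `z_um` (detection-axis coordinate) and
#'   `intensity`.
#' @export
sheetAxialProfile <- function(map, xPosition) {
  stopifnot(is(map, "BeamIntensityMap"))
  zr <- range(map@axialCoords)
  if (xPosition < zr[1] || xPosition > zr[2])
    stop("xPosition ", xPosition, " um lies outside the map's axial range [",
         format(zr[1], digits = 6), ", ", format(zr[2], digits = 6), "]",
         call. = FALSE)
  j <- which.min(abs(map@axialCoords - xPosition))
  data.frame(z_um = map@transverseCoords, intensity = map@intensity[, j])
}

#' Resample a sheet profile onto a PSF's axial grid
#'
#' Interpolates a [sheetAxialProfile()] onto the z coordinates of a
#' detection PSF, centring the profile's main peak on the PSF's focal
#' plane (z = 0). Values outside the profile are extended with zero.
#'
#' @param profile data.frame from [sheetAxialProfile()].
#' @param psf an [ImageStack3D-class] whose z grid to match.
#' @return numeric vector of length `dim(psf)[3]`.
#' @export
alignSheetProfile <- function(profile, psf) {
  stopIfNot3D(psf)
  zpsf <- stackAxisCoords(psf, "z")
  pk <- which.max(profile$intensity)
  z0 <- profile$z_um[pk]
  out <- stats::approx(profile$z_um - z0, profile$intensity, xout = zpsf)$y
  out[is.na(out)] <- 0
  out
}

#' Light-sheet system PSF
#'
#' Standard light-sheet image formation: the detection PSF is multiplied
#' along z by the illumination sheet profile and renormalized to unit sum.
#' A sheet narrower than the detection PSF therefore narrows the system
#' PSF axially; a uniform profile leaves it unchanged.
#'
#' @param illuminationProfile numeric vector of sheet intensities, one per
#'   z-plane of `det` (e.g. from [alignSheetProfile()]).
#' @param det detection PSF, an [ImageStack3D-class].
#' @return an [ImageStack3D-class] with unit sum.
#' @export
systemPSF <- function(illuminationProfile, det) {
  stopIfNot3D(det)
  nz <- dim(det@voxels)[3]
  if (length(illuminationProfile) != nz)
    stop("illumination profile has ", length(illuminationProfile),
         " samples but the detection PSF has ", nz, " z-planes",
         call. = FALSE)
  if (any(illuminationProfile < 0))
    stop("illumination profile must be non-negative", call. = FALSE)
  vox <- sweep(det@voxels, 3, illuminationProfile, "*")
  s <- sum(vox)
  if (s <= 0) stop("system PSF has zero total intensity", call. = FALSE)
  imageStack3D(vox / s, det@pitch)
}

## Rendering -----------------------------------------------------------------

# Rasterize one spherical bead into the truth array (in place via return).
# Spheres are volume-sampled at `sub`x sub-voxel resolution and box-averaged;
# beads not larger than half a voxel are deposited as trilinear deltas.
rasterizeBead <- function(truth, pitch, center, diameter, brightness,
                          sub = 4L) {
  d <- dim(truth)
  r <- diameter / 2
  cvox <- center / pitch + (floor(d / 2) + 1)   # fractional voxel index
  if (diameter <= min(pitch) / 2) {
    i0 <- floor(cvox); fr <- cvox - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- i0 + c(dx, dy, dz)
      if (all(ii >= 1) && all(ii <= d)) {
        w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
        truth[ii[1], ii[2], ii[3]] <- truth[ii[1], ii[2], ii[3]] +
          brightness * w
      }
    }
    return(truth)
  }
  lo <- pmax(1L, floor(cvox - r / pitch) - 1L)
  hi <- pmin(d, ceiling(cvox + r / pitch) + 1L)
  if (any(lo > hi)) return(truth)
  # sub-voxel sample offsets (voxel units), centred
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  occ <- array(0, hi - lo + 1L)
  axes <- lapply(1:3, function(i) seq.int(lo[i], hi[i]))
  for (ox in off) for (oy in off) for (oz in off) {
    px <- (axes[[1]] + ox - cvox[1]) * pitch[1]
    py <- (axes[[2]] + oy - cvox[2]) * pitch[2]
    pz <- (axes[[3]] + oz - cvox[3]) * pitch[3]
    inside <- outer(outer(px^2, py^2, "+"), pz^2, "+") <= r^2
    occ <- occ + inside
  }
  occ <- occ / sub^3
  tot <- sum(occ)
  if (tot > 0)
    truth[axes[[1]], axes[[2]], axes[[3]]] <-
      truth[axes[[1]], axes[[2]], axes[[3]]] + brightness * occ / tot
  truth
}

#' Render a noisy 3D stack from a bead phantom
#'
#' Expected counts are the volume-rasterized beads convolved with the PSF,
#' scaled by per-bead brightness, plus a constant background; with a seed,
#' Poisson noise is applied (deterministically for a fixed seed). Beads
#' whose centres fall outside the volume contribute only their in-volume
#' voxels, with a warning.
#'
#' @param phantom a [BeadPhantom-class].
#' @param psf system PSF, an [ImageStack3D-class]; its pitch must equal
#'   `pitch`.
#' @param dims output dimensions (voxels, x y z).
#' @param pitch output voxel pitch, um (x, y, z).
#' @param noiseSeed integer seed for Poisson noise, or `NULL` for the
#'   noiseless expectation.
#' @return an [ImageStack3D-class].
#' @export
renderStack <- function(phantom, psf, dims, pitch = voxelPitch(psf),
                        noiseSeed = NULL) {
  stopifnot(is(phantom, "BeadPhantom"))
  stopIfNot3D(psf)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (any(abs(psf@pitch - pitch) > 1e-9))
    stop("PSF pitch (", paste(psf@pitch, collapse = ", "),
         ") must equal the output pitch (", paste(pitch, collapse = ", "),
         ")", call. = FALSE)
  truth <- array(0, dims)
  halfExtent <- dims * pitch / 2
  bd <- phantom@beads
  if (nrow(bd)) {
    outside <- abs(bd$x) > halfExtent[1] | abs(bd$y) > halfExtent[2] |
      abs(bd$z) > halfExtent[3]
    if (any(outside))
      warning(sum(outside), " bead(s) outside the volume; contribution ",
              "clipped", call. = FALSE)
    for (i in seq_len(nrow(bd)))
      truth <- rasterizeBead(truth, pitch,
                             c(bd$x[i], bd$y[i], bd$z[i]),
                             bd$diameter[i], bd$brightness[i])
  }
  expected <- linearConvolve3(truth, psf@voxels) + phantom@background
  expected[expected < 0] <- 0
  vox <- if (is.null(noiseSeed)) expected else
    withSeed(noiseSeed,
             array(stats::rpois(length(expected), expected), dim(expected)))
  imageStack3D(vox, pitch)
}

#' Full width at half maximum of a spot along one axis
#'
#' Refines the stack's local maximum within 1 um of `seedPoint`, extracts
#' the 1D intensity profile through it along `axis`, subtracts the stack
#' background (median of the border voxels), refines the peak height with a
#' three-point parabola, and interpolates the two half-maximum crossings
#' linearly.
#'
#' @param stack an [ImageStack3D-class].
#' @param seedPoint approximate spot centre, um (x, y, z; physical
#'   coordinates with the volume centred on 0).
#' @param axis one of "x", "y", "z".
#' @return FWHM in um.
#' @export
measureFWHM <- function(stack, seedPoint, axis = c("z", "x", "y")) {
  stopIfNot3D(stack)
  axis <- match.arg(axis)
  d <- dim(stack@voxels)
  pitch <- stack@pitch
  cvox <- round(seedPoint / pitch + (floor(d / 2) + 1))
  rad <- pmax(1L, ceiling(1 / pitch))   # 1 um search radius
  lo <- pmax(1L, cvox - rad); hi <- pmin(d, cvox + rad)
  if (any(lo > hi)) stop("seed point outside the stack", call. = FALSE)
  box <- stack@voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  w <- which(box == max(box), arr.ind = TRUE)[1, ]
  pk <- lo + w - 1L
  # background: median of the stack's border voxels
  border <- c(stack@voxels[c(1, d[1]), , ], stack@voxels[, c(1, d[2]), ],
              stack@voxels[, , c(1, d[3])])
  bg <- stats::median(border)
  ax <- match(axis, c("x", "y", "z"))
  profile <- switch(axis,
    x = stack@voxels[, pk[2], pk[3]],
    y = stack@voxels[pk[1], , pk[3]],
    z = stack@voxels[pk[1], pk[2], ]) - bg
  ip <- pk[ax]
  if (profile[ip] <= 0 || max(profile) <= 0)
    stop("no peak above background near the seed point", call. = FALSE)
  coords <- centeredCoords(d[ax], pitch[ax])
  height <- profile[ip]
  if (ip > 1 && ip < length(profile)) {
    ref <- refinePeak(profile[ip - 1], profile[ip], profile[ip + 1])
    height <- unname(ref["height"])
  }
  half <- height / 2
  iL <- ip
  while (iL > 1 && profile[iL - 1] > half) iL <- iL - 1
  iR <- ip
  while (iR < length(profile) && profile[iR + 1] > half) iR <- iR + 1
  if (iL == 1 && profile[1] > half || iR == length(profile) &&
      profile[length(profile)] > half)
    stop("profile does not drop below half maximum within the stack ",
         "(truncated spot)", call. = FALSE)
  if (iL == ip && iR == ip) return(pitch[ax])
  xl <- crossingPosition(coords[iL - 1], profile[iL - 1], coords[iL],
                         profile[iL], half)
  xr <- crossingPosition(coords[iR], profile[iR], coords[iR + 1],
                         profile[iR + 1], half)
  xr - xl
}

#' Trim a PSF's axial extent to its significant planes
#'
#' A sheet-windowed system PSF concentrates its energy in a few z-planes;
#' trimming the negligible outer planes makes deconvolution kernels (and
#' their padding) much smaller. Planes are kept symmetrically around the
#' centre while their peak intensity exceeds `relTol` times the PSF
#' maximum; the result is renormalized to unit sum.
#'
#' @param psf an [ImageStack3D-class].
#' @param relTol relative plane-peak tolerance (default 1e-4).
#' @return the trimmed [ImageStack3D-class].
#' @export
trimPSF <- function(psf, relTol = 1e-4) {
  stopIfNot3D(psf)
  v <- psf@voxels
  nz <- dim(v)[3]
  cz <- floor(nz / 2) + 1L
  peaks <- apply(v, 3, max)
  keepHalf <- 0L
  while (cz - keepHalf - 1L >= 1L && cz + keepHalf + 1L <= nz &&
         (peaks[cz - keepHalf - 1L] > relTol * max(peaks) ||
          peaks[cz + keepHalf + 1L] > relTol * max(peaks)))
    keepHalf <- keepHalf + 1L
  keep <- (cz - keepHalf):(cz + keepHalf)
  out <- v[, , keep, drop = FALSE]
  imageStack3D(out / sum(out), psf@pitch)
}
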