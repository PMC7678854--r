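#' @rdname BeamIntensityMap-class
#' @export
setMethod("intensity", "BeamIntensityMap", function(x) x@intensity)

#' @rdname BeamIntensityMap-class
#' @export
setMethod("transverseCoords", "BeamIntensityMap",
          function(x) x@transverseCoords)

#' @rdname BeamIntensityMap-class
#' @export
setMethod("axialCoords", "BeamIntensityMap", function(x) x@axialCoords)

setMethod("show", "BeamIntensityMap", function(object) {
  cat("BeamIntensityMap:", nrow(object@intensity), "transverse x",
      ncol(object@intensity), "axial samples\n")
  cat("  transverse:", format(min(object@transverseCoords), digits = 5), "..",
      format(max(object@transverseCoords), digits = 5), "um;  axial:",
      format(min(object@axialCoords), digits = 6), "..",
      format(max(object@axialCoords), digits = 6), "um\n")
})

#' Sample the beam intensity over an axial window
#'
#' Computes |E(x', z)|^2 on a window of axial planes by advancing the stored
#' angular spectrum of `field` plane-by-plane (equivalent to repeated
#' angular-spectrum propagation from one stored spectrum). Offsets are taken
#' relative to the field's current plane, so a window centred downstream of a
#' focusing element samples the focal region; negative offsets within the
#' window re-sample the already-computed forward field and are permitted
#' here (unlike in [angularSpectrumPropagate()], which is a forward-only
#' contract).
#'
#' @param field a [SampledField-class] (typically just after the last lens).
#' @param zWindow full axial window length, um; `0` samples the single
#'   current plane.
#' @param axialPitch axial sample spacing, um (> 0).
#' @param zCenter window centre relative to the field's plane, um
#'   (e.g. the focal length of the last lens).
#' @param transverseWindow optional full transverse crop width, um; the crop
#'   is centred on the intensity maximum of the window's central plane.
#'   `NULL` keeps the full grid.
#' @return a [BeamIntensityMap-class]. Transverse coordinates are grid
#'   coordinates (um); axial coordinates are absolute positions
#'   `axialPosition(field) + zCenter + offset`.
#' @export
scanFocalRegion <- function(field, zWindow, axialPitch, zCenter = 0,
                            transverseWindow = NULL) {
  stopifnot(is(field, "SampledField"))
  if (axialPitch <= 0) stop("axialPitch must be positive", call. = FALSE)
  if (zWindow < 0) stop("zWindow must be non-negative", call. = FALSE)
  offsets <- if (zWindow == 0) 0 else {
    half <- zWindow / 2
    seq(-half, half, by = axialPitch)
  }
  n <- length(field@amplitude)
  dx <- field@gridPitch
  kx <- fftAngularFreq(n, dx)
  k <- wavenumber(field)
  spec <- stats::fft(field@amplitude)
  # sampling-validity heuristic: the spectral phase exp(i kz d) must stay
  # Nyquist-sampled over the band the field actually occupies
  p2 <- Mod(spec)^2
  occ <- abs(kx[p2 > 1e-9 * max(p2)])
  kxOcc <- min(max(occ), k * 0.999)
  if (kxOcc > 0) {
    dkx <- 2 * pi / (n * dx)
    dmax <- pi * sqrt(k^2 - kxOcc^2) / (kxOcc * dkx)
    if (max(abs(zCenter + offsets)) > dmax)
      warning("axial window extends beyond the sampling validity range (",
              format(dmax / 1e3, digits = 4), " mm) of this grid",
              call. = FALSE)
  }
  x <- centeredCoords(n, dx)

  planeIntensity <- function(d) {
    a <- stats::fft(spectralAdvance(spec, kx, k, d), inverse = TRUE) / n
    Mod(a)^2
  }

  keep <- seq_len(n)
  if (!is.null(transverseWindow)) {
    icen <- which(offsets == 0)
    if (!length(icen)) icen <- which.min(abs(offsets))
    Icen <- planeIntensity(zCenter + offsets[icen[1]])
    pk <- which.max(Icen)
    hw <- max(1L, round(transverseWindow / (2 * dx)))
    keep <- max(1L, pk - hw):min(n, pk + hw)
  }
  img <- matrix(0, length(keep), length(offsets))
  for (j in seq_along(offsets))
    img[, j] <- planeIntensity(zCenter + offsets[j])[keep]
  new("BeamIntensityMap", intensity = img, transverseCoords = x[keep],
      axialCoords = field@axialPosition + zCenter + offsets)
}

## Main-lobe metrology -------------------------------------------------------

# Locate the lobe peak in one intensity profile. With no previous centre the
# global maximum is used; otherwise the maximum within +-searchRadius of the
# previous centre (nearest-lobe continuity, so side lobes of an Airy profile
# are not jumped to). Returns index of the peak sample.
locateLobe <- function(I, xcoords, previousCenter, searchRadius) {
  if (is.null(previousCenter)) return(which.max(I))
  pitch <- xcoords[2] - xcoords[1]
  ctr <- which.min(abs(xcoords - previousCenter))
  hw <- max(1L, round(searchRadius / pitch))
  win <- max(1L, ctr - hw):min(length(I), ctr + hw)
  win[which.max(I[win])]
}

# 1/e-intensity diameter around a located lobe: walk outwards from the peak
# until the profile first drops below peak/e, interpolating the crossings
# linearly. Degenerate single-sample lobes return one pitch.
lobeDiameter <- function(I, xcoords, peakIdx, peakHeight) {
  n <- length(I)
  thr <- peakHeight / exp(1)
  pitch <- xcoords[2] - xcoords[1]
  iL <- peakIdx
  while (iL > 1 && I[iL - 1] > thr) iL <- iL - 1
  iR <- peakIdx
  while (iR < n && I[iR + 1] > thr) iR <- iR + 1
  if (iL == peakIdx && iR == peakIdx) return(pitch)
  xl <- if (iL > 1)
    crossingPosition(xcoords[iL - 1], I[iL - 1], xcoords[iL], I[iL], thr)
  else xcoords[1]
  xr <- if (iR < n)
    crossingPosition(xcoords[iR], I[iR], xcoords[iR + 1], I[iR + 1], thr)
  else xcoords[n]
  xr - xl
}

#' Main-lobe centre, 1/e diameter and peak of one axial plane
#'
#' The lobe centre is the plane's intensity maximum, refined to sub-sample
#' precision by a three-point parabola; for self-bending (Airy) beams pass
#' the previous plane's centre so the tracker follows the same lobe instead
#' of jumping to a side lobe. The diameter is the full width at
#' intensity = peak/e around that lobe, linearly interpolated between
#' samples; an isolated single-sample lobe reports one grid pitch.
#'
#' @param map a [BeamIntensityMap-class].
#' @param planeIndex column (axial plane) index.
#' @param previousCenter optional centre (um) of the lobe in the previous
#'   plane, for nearest-lobe continuity tracking.
#' @param searchRadius half-width (um) of the tracking search window
#'   (default 10).
#' @return list with `lobeCenter` (um), `oneOverEDiameter` (um),
#'   `peakIntensity`.
#' @export
mainLobeMetrics <- function(map, planeIndex, previousCenter = NULL,
                            searchRadius = 10) {
  stopifnot(is(map, "BeamIntensityMap"))
  I <- map@intensity[, planeIndex]
  if (all(I <= 0))
    stop("plane ", planeIndex, " contains no positive intensity",
         call. = FALSE)
  x <- map@transverseCoords
  pk <- locateLobe(I, x, previousCenter, searchRadius)
  pitch <- x[2] - x[1]
  if (pk > 1 && pk < length(I)) {
    ref <- refinePeak(I[pk - 1], I[pk], I[pk + 1])
    center <- x[pk] + ref["offset"] * pitch
    height <- ref["height"]
  } else {
    center <- x[pk]; height <- I[pk]
  }
  list(lobeCenter = unname(center),
       oneOverEDiameter = lobeDiameter(I, x, pk, unname(height)),
       peakIntensity = unname(height))
}

#' Per-plane main-lobe metrics for a whole map
#'
#' Applies [mainLobeMetrics()] to every axial plane with nearest-lobe
#' continuity tracking (first plane: global maximum).
#'
#' @inheritParams mainLobeMetrics
#' @return data.frame with columns `z_um`, `lobe_center_um`, `diameter_um`,
#'   `peak`.
#' @export
beamMetrics <- function(map, searchRadius = 10) {
  stopifnot(is(map, "BeamIntensityMap"))
  nz <- ncol(map@intensity)
  out <- data.frame(z_um = map@axialCoords, lobe_center_um = NA_real_,
                    diameter_um = NA_real_, peak = NA_real_)
  prev <- NULL
  for (j in seq_len(nz)) {
    m <- mainLobeMetrics(map, j, previousCenter = prev,
                         searchRadius = searchRadius)
    out$lobe_center_um[j] <- m$lobeCenter
    out$diameter_um[j] <- m$oneOverEDiameter
    out$peak[j] <- m$peakIntensity
    prev <- m$lobeCenter
  }
  out
}

#' Diffraction-free length of a beam map
#'
#' Length of the longest contiguous axial interval over which the tracked
#' main-lobe 1/e diameter stays within `widthToleranceFactor` times its
#' minimum over the map. The default factor sqrt(2) is the Gaussian-confocal
#' analogue (a Gaussian beam satisfies it exactly over two Rayleigh ranges).
#'
#' @inheritParams mainLobeMetrics
#' @param widthToleranceFactor tolerance factor (> 1, default `sqrt(2)`).
#' @return diffraction-free length, um.
#' @export
diffractionFreeLength <- function(map, widthToleranceFactor = sqrt(2),
                                  searchRadius = 10) {
  if (widthToleranceFactor <= 1)
    stop("widthToleranceFactor must be > 1", call. = FALSE)
  met <- beamMetrics(map, searchRadius = searchRadius)
  wmin <- min(met$diameter_um)
  ok <- met$diameter_um <= widthToleranceFactor * wmin
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- 0
  for (q in which(runs$values))
    best <- max(best, met$z_um[ends[q]] - met$z_um[starts[q]])
  best
}

## Gaussian reference --------------------------------------------------------

#' Construct a Gaussian waist model
#'
#' @param waist beam waist w0, um (default 1.2).
#' @param wavelength wavelength, um (default 0.488).
#' @param refractiveIndex medium index (default 1).
#' @return a [GaussianWaistModel-class].
#' @export
gaussianWaistModel <- function(waist = 1.2, wavelength = 0.488,
                               refractiveIndex = 1) {
  new("GaussianWaistModel", waist = waist, wavelength = wavelength,
      refractiveIndex = refractiveIndex)
}

#' @rdname GaussianWaistModel-class
#' @export
setMethod("rayleighRange", "GaussianWaistModel", function(x)
  pi * x@waist^2 * x@refractiveIndex / x@wavelength)

#' @describeIn gaussianWaist closed form
#'   \eqn{w(z) = w_0\sqrt{1 + (z/z_r)^2}} with
#'   \eqn{z_r = \pi w_0^2 n/\lambda}.
#' @export
setMethod("gaussianWaist", "GaussianWaistModel", function(model, z) {
  zr <- rayleighRange(model)
  model@waist * sqrt(1 + (z / zr)^2)
})

setMethod("show", "GaussianWaistModel", function(object) {
  cat("GaussianWaistModel: w0 =", object@waist, "um, lambda =",
      object@wavelength, "um, n =", object@refractiveIndex,
      "-> z_r =", format(rayleighRange(object), digits = 5), "um\n")
})

## High-level driver ---------------------------------------------------------

#' Simulate the illumination beam through a lens train
#'
#' Samples the source onto the grid, propagates it through the train, and
#' scans the intensity over an axial window centred on the focus of the last
#' lens. With the default source, train and sampling this reproduces the
#' cubic-phase Airy illumination of the default seven-lens layout
#' (wavelength 0.488 um, w0 = 4.3 mm, alpha = 5.38 mm^-3, grid 2^20 at
#' 0.2 um pitch).
#'
#' @param source a [GaussianCubicSource-class].
#' @param train an [OpticalTrain-class] ending at the last lens.
#' @param gridSize transverse samples (power of two, default 2^20).
#' @param gridPitch transverse pitch, um (default 0.2).
#' @param wavelength vacuum wavelength, um (default 0.488).
#' @param refractiveIndex medium index (default 1).
#' @param zWindow axial window, um (default the train's `finalScanRange`).
#' @param axialPitch axial pitch, um (default 0.2).
#' @param transverseWindow transverse crop width, um (default 400; `NULL`
#'   keeps the full grid, which for the default grid is ~1.7 GB of map).
#' @return a [BeamIntensityMap-class].
#' @export
simulateBeam <- function(source = gaussianCubicSource(waist = 4.3,
                                                      cubicScaling = 5.38),
                         train = airyTrain(),
                         gridSize = 2^20, gridPitch = 0.2,
                         wavelength = 0.488, refractiveIndex = 1,
                         zWindow = NULL, axialPitch = 0.2,
                         transverseWindow = 400) {
  if (is.null(zWindow)) zWindow <- train@finalScanRange * 1e3
  fld <- makeSourceField(source, gridSize, gridPitch, wavelength,
                         refractiveIndex)
  fld <- propagateTrain(fld, train)
  scanFocalRegion(fld, zWindow = zWindow, axialPitch = axialPitch,
                  zCenter = lastFocalLength(train),
                  transverseWindow = transverseWindow)
}
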