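#' Construct a sampled field
#'
#' Low-level constructor; most workflows start from [makeSourceField()].
#'
#' @param amplitude complex vector of field samples; length must be a power
#'   of two.
#' @param gridPitch transverse sample spacing, um.
#' @param wavelength vacuum wavelength, um.
#' @param refractiveIndex medium index (default 1).
#' @param axialPosition current axial position, um (default 0).
#' @return a [SampledField-class].
#' @export
sampledField <- function(amplitude, gridPitch, wavelength,
                         refractiveIndex = 1, axialPosition = 0) {
  new("SampledField", amplitude = as.complex(amplitude),
      gridPitch = gridPitch, wavelength = wavelength,
      refractiveIndex = refractiveIndex, axialPosition = axialPosition)
}

#' Construct a Gaussian cubic-phase source
#'
#' @param waist 1/e field half-width w0 of the Gaussian, mm.
#' @param amplitudeScale peak amplitude A (default 1).
#' @param cubicScaling cubic phase scaling alpha, mm^-3 (default 0: plain
#'   Gaussian).
#' @return a [GaussianCubicSource-class].
#' @export
gaussianCubicSource <- function(waist, amplitudeScale = 1, cubicScaling = 0) {
  new("GaussianCubicSource", waist = waist, amplitudeScale = amplitudeScale,
      cubicScaling = cubicScaling)
}

#' Sample a Gaussian cubic-phase source onto a transverse grid
#'
#' Evaluates \eqn{E_0(x) = A \exp(-x^2/w_0^2)\exp(i\,\alpha x^3/3)} on a
#' centred grid of `gridSize` points at `gridPitch` um. The source waist and
#' cubic scaling are given in mm and mm^-3 and converted internally.
#'
#' The grid must span at least three waists on either side and may not clip
#' more than 0.1\% of the Gaussian power, otherwise the call is rejected with
#' a sizing message.
#'
#' @param source a [GaussianCubicSource-class].
#' @param gridSize number of samples (power of two).
#' @param gridPitch sample spacing, um.
#' @param wavelength vacuum wavelength, um.
#' @param refractiveIndex medium index (default 1).
#' @return a [SampledField-class] at axial position 0.
#' @examples
#' src <- gaussianCubicSource(waist = 4.3, cubicScaling = 5.38)
#' fld <- makeSourceField(src, gridSize = 2^17, gridPitch = 0.25,
#'                        wavelength = 0.488)
#' @export
makeSourceField <- function(source, gridSize, gridPitch, wavelength,
                            refractiveIndex = 1) {
  stopifnot(is(source, "GaussianCubicSource"))
  w0 <- source@waist * 1e3           # mm -> um
  alpha <- source@cubicScaling * 1e-9  # mm^-3 -> um^-3
  halfSpan <- gridSize * gridPitch / 2
  if (halfSpan < 3 * w0)
    stop("grid too small: spans +-", format(halfSpan / 1e3, digits = 4),
         " mm but must cover at least +-3 w0 = +-",
         format(3 * w0 / 1e3, digits = 4),
         " mm; increase gridSize or gridPitch", call. = FALSE)
  # power fraction of exp(-2 x^2 / w0^2) outside the grid
  clipped <- 2 * stats::pnorm(-2 * halfSpan / w0)
  if (clipped > 1e-3)
    stop("grid clips ", format(100 * clipped, digits = 3),
         "% of the source power (limit 0.1%); enlarge the grid",
         call. = FALSE)
  x <- centeredCoords(gridSize, gridPitch)
  amp <- source@amplitudeScale * exp(-x^2 / w0^2) *
    exp(1i * (alpha / 3) * x^3)
  sampledField(amp, gridPitch, wavelength, refractiveIndex, axialPosition = 0)
}

## Accessors ----------------------------------------------------------------

#' @rdname SampledField-class
#' @export
setMethod("amplitude", "SampledField", function(x) x@amplitude)

#' @rdname SampledField-class
#' @export
setMethod("gridPitch", "SampledField", function(x) x@gridPitch)

#' @rdname SampledField-class
#' @export
setMethod("wavelength", "SampledField", function(x) x@wavelength)

#' @rdname SampledField-class
#' @export
setMethod("refractiveIndex", "SampledField", function(x) x@refractiveIndex)

#' @rdname SampledField-class
#' @export
setMethod("axialPosition", "SampledField", function(x) x@axialPosition)

#' @rdname SampledField-class
#' @export
setMethod("fieldCoordinates", "SampledField", function(x)
  centeredCoords(length(x@amplitude), x@gridPitch))

#' @rdname SampledField-class
#' @export
setMethod("wavenumber", "SampledField", function(x)
  2 * pi * x@refractiveIndex / x@wavelength)

#' @rdname SampledField-class
#' @export
setMethod("totalPower", "SampledField", function(x)
  sum(Mod(x@amplitude)^2) * x@gridPitch)

setMethod("show", "SampledField", function(object) {
  n <- length(object@amplitude)
  cat("SampledField:", n, "samples,",
      format(object@gridPitch, digits = 4), "um pitch (span",
      format(n * object@gridPitch / 1e3, digits = 4), "mm)\n")
  cat("  wavelength", object@wavelength, "um, n =", object@refractiveIndex,
      ", z =", format(object@axialPosition / 1e3, digits = 6), "mm\n")
})

## Propagation primitives ----------------------------------------------------

# Spectral free-space transfer: multiply the angular spectrum by
# exp(i kz d), kz = sqrt(k^2 - kx^2); evanescent components are zeroed.
# Used by both the public propagation method and the focal-region scan
# (which may advance the same stored spectrum by signed offsets).
spectralAdvance <- function(spectrum, kx, k, distance) {
  prop <- kx^2 <= k^2
  kz <- numeric(length(kx))
  kz[prop] <- sqrt(k^2 - kx[prop]^2)
  out <- complex(length.out = length(spectrum))
  out[prop] <- spectrum[prop] * exp(1i * kz[prop] * distance)
  out
}

#' @describeIn angularSpectrumPropagate advance a field by `distance` um via
#'   spectrum multiplication with \eqn{\exp(i k_z d)},
#'   \eqn{k_z = \sqrt{k^2 - k_x^2}}; evanescent components
#'   (\eqn{k_x^2 > k^2}) are suppressed. Total power over propagating
#'   components is conserved to relative tolerance 1e-9. Negative distances
#'   (backpropagation) are out of contract and raise an error.
#' @export
setMethod("angularSpectrumPropagate", "SampledField",
  function(field, distance) {
    if (length(distance) != 1L || !is.finite(distance))
      stop("distance must be a single finite number (um)", call. = FALSE)
    if (distance < 0)
      stop("backpropagation (negative distance) is out of contract",
           call. = FALSE)
    if (distance == 0) return(field)
    n <- length(field@amplitude)
    kx <- fftAngularFreq(n, field@gridPitch)
    k <- wavenumber(field)
    spec <- stats::fft(field@amplitude)
    amp <- stats::fft(spectralAdvance(spec, kx, k, distance),
                      inverse = TRUE) / n
    initialize(field, amplitude = amp,
               axialPosition = field@axialPosition + distance)
  })

#' @describeIn applyThinLens multiply the field pointwise by the thin-lens
#'   transmission \eqn{T(x) = \exp(-i (2\pi/\lambda) x^2 / 2f)}. A pure
#'   phase element: moduli are unchanged and power is exactly conserved.
#' @export
setMethod("applyThinLens", "SampledField", function(field, focalLength) {
  if (length(focalLength) != 1L || !is.finite(focalLength) ||
      focalLength <= 0)
    stop("focalLength must be a single positive number (cm)", call. = FALSE)
  f <- focalLength * 1e4  # cm -> um
  x <- fieldCoordinates(field)
  tl <- exp(-1i * (2 * pi / field@wavelength) * x^2 / (2 * f))
  initialize(field, amplitude = field@amplitude * tl)
})
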