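#' @import methods
NULL

#' Complex optical field sampled on a uniform 1D transverse grid
#'
#' `SampledField` is the currency of the beam simulator: a complex amplitude
#' sampled on a uniform transverse grid (one transverse axis; the propagation
#' model is two-dimensional), together with the wavelength, refractive index
#' and current axial position. The grid length must be a power of two so that
#' angular-spectrum steps map onto radix-2 FFTs.
#'
#' All lengths are in micrometres.
#'
#' @slot amplitude complex vector, the field samples (dimensionless units).
#' @slot gridPitch numeric(1), transverse sample spacing in um.
#' @slot wavelength numeric(1), vacuum wavelength in um.
#' @slot refractiveIndex numeric(1), medium refractive index (>= 1).
#' @slot axialPosition numeric(1), current axial position z in um.
#'
#' @seealso [makeSourceField()], [angularSpectrumPropagate()],
#'   [applyThinLens()], [propagateTrain()]
#' @export
setClass("SampledField",
  representation(
    amplitude = "complex",
    gridPitch = "numeric",
    wavelength = "numeric",
    refractiveIndex = "numeric",
    axialPosition = "numeric"
  ),
  prototype(refractiveIndex = 1, axialPosition = 0)
)

setValidity("SampledField", function(object) {
  n <- length(object@amplitude)
  msg <- character()
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    msg <- c(msg, "grid length must be a power of two (>= 2)")
  if (length(object@gridPitch) != 1L || !is.finite(object@gridPitch) ||
      object@gridPitch <= 0)
    msg <- c(msg, "gridPitch must be a single positive number")
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number")
  if (length(object@refractiveIndex) != 1L || object@refractiveIndex < 1)
    msg <- c(msg, "refractiveIndex must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Gaussian illumination of a cubic phase mask
#'
#' Describes the source field at the spatial-light-modulator plane: a Gaussian
#' of 1/e field half-width `waist` carrying the cubic phase
#' \eqn{\exp(i \alpha x^3 / 3)}. With `cubicScaling = 0` the source
#' degenerates to a plain Gaussian. Source dimensions follow optical-bench
#' convention (mm, mm^-3) and are converted to um when the field is sampled.
#'
#' @slot waist numeric(1), 1/e field half-width w0 in mm.
#' @slot amplitudeScale numeric(1), peak amplitude A (dimensionless).
#' @slot cubicScaling numeric(1), cubic phase scaling alpha in mm^-3 (>= 0).
#'
#' @export
setClass("GaussianCubicSource",
  representation(
    waist = "numeric",
    amplitudeScale = "numeric",
    cubicScaling = "numeric"
  ),
  prototype(amplitudeScale = 1, cubicScaling = 0)
)

setValidity("GaussianCubicSource", function(object) {
  msg <- character()
  if (length(object@waist) != 1L || object@waist <= 0)
    msg <- c(msg, "waist must be a single positive number (mm)")
  if (length(object@cubicScaling) != 1L || object@cubicScaling < 0)
    msg <- c(msg, "cubicScaling must be >= 0 (mm^-3)")
  if (length(object@amplitudeScale) != 1L || object@amplitudeScale <= 0)
    msg <- c(msg, "amplitudeScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Ordered train of thin lenses and free-space segments
#'
#' Elements are visited in order; each is a list with `type = "lens"` and
#' `f_cm` (focal length, cm) or `type = "gap"` and `d_cm` (distance, cm).
#' `finalScanRange` records the axial sampling window (mm) used around the
#' focus of the last lens.
#'
#' @slot elements list of lens/gap element descriptions.
#' @slot finalScanRange numeric(1), axial scan window around the last focus, mm.
#'
#' @seealso [opticalTrain()], [airyTrain()], [propagateTrain()]
#' @export
setClass("OpticalTrain",
  representation(elements = "list", finalScanRange = "numeric"),
  prototype(elements = list(), finalScanRange = 4)
)

setValidity("OpticalTrain", function(object) {
  msg <- character()
  for (el in object@elements) {
    if (!is.list(el) || is.null(el$type) ||
        !el$type %in% c("lens", "gap")) {
      msg <- c(msg, "each element must be a list with type 'lens' or 'gap'")
      break
    }
    if (el$type == "lens" && (is.null(el$f_cm) || el$f_cm <= 0))
      msg <- c(msg, "lens focal lengths must be positive (f_cm)")
    if (el$type == "gap" && (is.null(el$d_cm) || el$d_cm <= 0))
      msg <- c(msg, "gap distances must be positive (d_cm)")
  }
  if (length(object@finalScanRange) != 1L || object@finalScanRange <= 0)
    msg <- c(msg, "finalScanRange must be positive (mm)")
  if (length(msg)) unique(msg) else TRUE
})

#' Transverse-by-axial beam intensity map
#'
#' Non-negative intensity |E(x', z)|^2 sampled on a uniform 2D grid: rows are
#' transverse positions x' (um), columns axial positions z (um). Produced by
#' [scanFocalRegion()] and consumed by the beam metrology functions.
#'
#' @slot intensity numeric matrix, rows transverse, columns axial.
#' @slot transverseCoords numeric, transverse sample positions in um.
#' @slot axialCoords numeric, axial sample positions in um.
#'
#' @export
setClass("BeamIntensityMap",
  representation(
    intensity = "matrix",
    transverseCoords = "numeric",
    axialCoords = "numeric"
  )
)

setValidity("BeamIntensityMap", function(object) {
  msg <- character()
  if (nrow(object@intensity) != length(object@transverseCoords))
    msg <- c(msg, "nrow(intensity) must match length(transverseCoords)")
  if (ncol(object@intensity) != length(object@axialCoords))
    msg <- c(msg, "ncol(intensity) must match length(axialCoords)")
  if (any(!is.finite(object@intensity)) || any(object@intensity < 0))
    msg <- c(msg, "intensity must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Closed-form Gaussian beam waist model
#'
#' Holds the waist w0, wavelength and refractive index from which the Rayleigh
#' range z_r = pi w0^2 n / lambda and the waist law
#' w(z) = w0 sqrt(1 + (z/z_r)^2) follow.
#'
#' @slot waist numeric(1), beam waist w0 in um (default 1.2).
#' @slot wavelength numeric(1), wavelength in um.
#' @slot refractiveIndex numeric(1), medium index.
#'
#' @seealso [gaussianWaist()], [rayleighRange()]
#' @export
setClass("GaussianWaistModel",
  representation(
    waist = "numeric",
    wavelength = "numeric",
    refractiveIndex = "numeric"
  ),
  prototype(waist = 1.2, wavelength = 0.488, refractiveIndex = 1)
)

setValidity("GaussianWaistModel", function(object) {
  if (object@waist <= 0 || object@wavelength <= 0 ||
      object@refractiveIndex < 1)
    "waist and wavelength must be positive, refractiveIndex >= 1"
  else TRUE
})

#' Detection-arm optical parameters
#'
#' @slot numericalAperture numeric(1), detection NA (default 0.7).
#' @slot emissionWavelength numeric(1), emission wavelength in um
#'   (default 0.525, centre of a 525/50 bandpass).
#' @slot mediumIndex numeric(1), sample-medium refractive index.
#'
#' @export
setClass("DetectionParams",
  representation(
    numericalAperture = "numeric",
    emissionWavelength = "numeric",
    mediumIndex = "numeric"
  ),
  prototype(numericalAperture = 0.7, emissionWavelength = 0.525,
            mediumIndex = 1.33)
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@numericalAperture <= 0)
    msg <- c(msg, "numericalAperture must be positive")
  if (object@numericalAperture >= object@mediumIndex)
    msg <- c(msg, "numericalAperture must be smaller than mediumIndex")
  if (object@emissionWavelength <= 0)
    msg <- c(msg, "emissionWavelength must be positive")
  if (length(msg)) msg else TRUE
})

#' 3D intensity stack with anisotropic voxel pitch
#'
#' Non-negative voxel intensities on a 3D grid with physical voxel pitch
#' (x, y, z) in um. Used for PSFs, rendered phantom stacks, and as the input
#' and output of deconvolution. The z pitch defaults to 0.2 um, the axial
#' step used for acquisition stacks.
#'
#' @slot voxels 3D numeric array of non-negative intensities.
#' @slot pitch numeric(3), voxel pitch (x, y, z) in um.
#'
#' @seealso [imageStack3D()], [readImageStack()], [writeImageStack()]
#' @export
setClass("ImageStack3D",
  representation(voxels = "array", pitch = "numeric")
)

setValidity("ImageStack3D", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (any(!is.finite(object@voxels)) || any(object@voxels < 0))
    msg <- c(msg, "voxels must be finite and non-negative")
  if (length(object@pitch) != 3L || any(object@pitch <= 0))
    msg <- c(msg, "pitch must be three positive numbers (x, y, z in um)")
  if (length(msg)) msg else TRUE
})

#' 2D optical-phase map
#'
#' Optical phase in radians on a uniform 2D pixel grid; the input of the QPI
#' analysis chain.
#'
#' @slot phase numeric matrix of phase values (radians).
#' @slot pixelPitch numeric(1), pixel pitch in um.
#'
#' @export
setClass("PhaseImage",
  representation(phase = "matrix", pixelPitch = "numeric")
)

setValidity("PhaseImage", function(object) {
  msg <- character()
  if (any(!is.finite(object@phase)))
    msg <- c(msg, "phase values must be finite")
  if (length(object@pixelPitch) != 1L || object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Field of fluorescent beads in a clear matrix
#'
#' @slot beads data.frame with columns `x`, `y`, `z` (centre, um),
#'   `diameter` (um) and `brightness` (expected photons per bead).
#' @slot background numeric(1), expected photons per voxel.
#'
#' @seealso [beadPhantom()], [renderStack()]
#' @export
setClass("BeadPhantom",
  representation(beads = "data.frame", background = "numeric"),
  prototype(background = 0)
)

setValidity("BeadPhantom", function(object) {
  need <- c("x", "y", "z", "diameter", "brightness")
  msg <- character()
  if (!all(need %in% names(object@beads)))
    msg <- c(msg, paste("beads must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (nrow(object@beads) && any(object@beads$diameter <= 0))
      msg <- c(msg, "bead diameters must be positive")
    if (nrow(object@beads) && any(object@beads$brightness < 0))
      msg <- c(msg, "bead brightness must be non-negative")
  }
  if (object@background < 0)
    msg <- c(msg, "background must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Richardson-Lucy settings
#'
#' @slot iterations integer(1), number of multiplicative updates (default 50).
#' @slot clipNegatives logical(1), clamp tiny negative excursions to zero.
#' @slot epsilon numeric(1), division guard on the ratio step.
#'
#' @export
setClass("DeconvolutionSettings",
  representation(
    iterations = "integer",
    clipNegatives = "logical",
    epsilon = "numeric"
  ),
  prototype(iterations = 50L, clipNegatives = TRUE, epsilon = 1e-12)
)

setValidity("DeconvolutionSettings", function(object) {
  msg <- character()
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic scene of yeast-like cells with lipid droplets
#'
#' The ground-truthed specimen description used by the phantom generators:
#' ellipsoidal cells (in-plane major axis drawn around 5.3 um), each with
#' zero or more higher-phase lipid droplets, plus the per-cell fluorophore
#' truth (expression level, localized/diffusive mode, set surface-coverage
#' fraction). The seed fixes all randomness.
#'
#' @slot cells data.frame, one row per cell: `x`, `y` (centre, um), `major`
#'   (major axis, um), `aspect` (major/minor ratio), `orientation` (rad),
#'   `cytosolPhaseScale` (rad per um of chord).
#' @slot lds data.frame, one row per droplet: `cell`, `dx`, `dy` (offset from
#'   the cell centre, um), `diameter` (um), `phaseScale` (excess rad per um).
#' @slot truth data.frame, one row per cell: `cell`, `expression`,
#'   `mode` ("localized"/"diffusive"), `coverage` (fraction in [0, 1]),
#'   `dryMass` (pg, analytic).
#' @slot fieldSize numeric(2), lateral field extent (um).
#' @slot seed integer(1), the seed the scene was generated from.
#' @slot params list, the generator parameters used.
#'
#' @seealso [generateCellScene()], [sceneToPhase()], [sceneToFluor()]
#' @export
setClass("CellScene",
  representation(
    cells = "data.frame",
    lds = "data.frame",
    truth = "data.frame",
    fieldSize = "numeric",
    seed = "integer",
    params = "list"
  )
)

setValidity("CellScene", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize <= 0))
    msg <- c(msg, "fieldSize must be two positive numbers (um)")
  if (nrow(object@lds)) {
    if (any(object@lds$diameter <= 0))
      msg <- c(msg, "LD diameters must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a Mann-Whitney rank test
#'
#' @slot uStatistic numeric(1), the U statistic of the first sample.
#' @slot pValue numeric(1), two-sided p value.
#' @slot method character(1), "exact" or "normal-approximation".
#' @slot sampleSizes integer(2), (n1, n2).
#'
#' @seealso [mannWhitney()]
#' @export
setClass("RankTestResult",
  representation(
    uStatistic = "numeric",
    pValue = "numeric",
    method = "character",
    sampleSizes = "integer"
  )
)

setValidity("RankTestResult", function(object) {
  n1 <- object@sampleSizes[1]; n2 <- object@sampleSizes[2]
  msg <- character()
  if (object@uStatistic < 0 || object@uStatistic > n1 * n2)
    msg <- c(msg, "U must lie in [0, n1*n2]")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "p must lie in [0, 1]")
  if (!object@method %in% c("exact", "normal-approximation"))
    msg <- c(msg, "method must be 'exact' or 'normal-approximation'")
  if (length(msg)) msg else TRUE
})
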