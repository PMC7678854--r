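#' @rdname SampledField-class
#' @param object,x an object.
#' @param ... further arguments for methods.
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname SampledField-class
#' @export
setGeneric("gridPitch", function(x) standardGeneric("gridPitch"))

#' @rdname SampledField-class
#' @export
setGeneric("wavelength", function(x) standardGeneric("wavelength"))

#' @rdname SampledField-class
#' @export
setGeneric("refractiveIndex", function(x) standardGeneric("refractiveIndex"))

#' @rdname SampledField-class
#' @export
setGeneric("axialPosition", function(x) standardGeneric("axialPosition"))

#' @rdname SampledField-class
#' @export
setGeneric("fieldCoordinates", function(x) standardGeneric("fieldCoordinates"))

#' @rdname SampledField-class
#' @export
setGeneric("wavenumber", function(x) standardGeneric("wavenumber"))

#' @rdname SampledField-class
#' @export
setGeneric("totalPower", function(x) standardGeneric("totalPower"))

#' Propagate a field through free space by the angular-spectrum method
#'
#' @param field a [SampledField-class].
#' @param distance propagation distance in um (non-negative).
#' @return the advanced [SampledField-class].
#' @export
setGeneric("angularSpectrumPropagate",
           function(field, distance) standardGeneric("angularSpectrumPropagate"))

#' Apply a thin-lens quadratic phase to a field
#'
#' @param field a [SampledField-class].
#' @param focalLength focal length in cm (positive).
#' @return the [SampledField-class] after the lens.
#' @export
setGeneric("applyThinLens",
           function(field, focalLength) standardGeneric("applyThinLens"))

#' Propagate a field through an ordered lens/gap train
#'
#' @param field a [SampledField-class].
#' @param train an [OpticalTrain-class].
#' @return the [SampledField-class] after the final element.
#' @export
setGeneric("propagateTrain",
           function(field, train) standardGeneric("propagateTrain"))

#' @rdname BeamIntensityMap-class
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname BeamIntensityMap-class
#' @export
setGeneric("transverseCoords", function(x) standardGeneric("transverseCoords"))

#' @rdname BeamIntensityMap-class
#' @export
setGeneric("axialCoords", function(x) standardGeneric("axialCoords"))

#' @rdname ImageStack3D-class
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageStack3D-class
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))

#' @rdname PhaseImage-class
#' @export
setGeneric("phaseValues", function(x) standardGeneric("phaseValues"))

#' @rdname PhaseImage-class
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname GaussianWaistModel-class
#' @export
setGeneric("rayleighRange", function(x) standardGeneric("rayleighRange"))

#' Gaussian beam waist at an axial position
#'
#' @param model a [GaussianWaistModel-class].
#' @param z axial position(s) in um, relative to the waist.
#' @return waist w(z) in um, vectorised over `z`.
#' @export
setGeneric("gaussianWaist",
           function(model, z) standardGeneric("gaussianWaist"))

#' @rdname RankTestResult-class
#' @export
setGeneric("uStatistic", function(x) standardGeneric("uStatistic"))

#' @rdname RankTestResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
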