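# Shared fixtures for the optical tests. Everything is computed in code;
# the heavier objects are built once when the helpers load and reused.

# Single-lens focusing train (gap f then lens f), f in cm.
singleLensTrain <- function(f_cm) {
  opticalTrain(list(list(type = "gap", d_cm = f_cm),
                    list(type = "lens", f_cm = f_cm)))
}

# A small cubic-phase beam brought to focus by one lens: an Airy-like
# light-sheet profile with a handful of side lobes, cheap enough for unit
# tests. Focus sits at 2e4 um absolute (1 cm gap + 1 cm focal length).
miniAiryMap <- local({
  cache <- NULL
  function(alpha = 20, waist = 0.5, zWindow = 400, axialPitch = 2) {
    key <- paste(alpha, waist, zWindow, axialPitch)
    if (!is.null(cache) && cache$key == key) return(cache$map)
    src <- gaussianCubicSource(waist = waist, cubicScaling = alpha)
    fld <- makeSourceField(src, 2^14, 0.2, 0.488)
    fld <- propagateTrain(fld, singleLensTrain(1))
    map <- suppressWarnings(
      scanFocalRegion(fld, zWindow, axialPitch, zCenter = 1e4,
                      transverseWindow = 160))
    cache <<- list(key = key, map = map)
    map
  }
})

# Denser cubic modulation: main lobe plus >= 3 clear side lobes.
miniAiryLobedMap <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    src <- gaussianCubicSource(waist = 0.6, cubicScaling = 40)
    fld <- makeSourceField(src, 2^15, 0.2, 0.488)
    fld <- propagateTrain(fld, singleLensTrain(1))
    cache <<- scanFocalRegion(fld, 400, 2, zCenter = 1e4,
                              transverseWindow = 160)
    cache
  }
})

# Gaussian beam sampled at its waist (w0 in um), used for closed-form
# comparisons.
gaussianWaistField <- function(w0 = 1.2, gridSize = 2^12, pitch = 0.05,
                               wavelength = 0.488) {
  src <- gaussianCubicSource(waist = w0 / 1e3, cubicScaling = 0)
  makeSourceField(src, gridSize, pitch, wavelength)
}

# Count local maxima above a relative intensity floor in a 1D profile.
countLobes <- function(I, relFloor = 0.02) {
  loc <- which(diff(sign(diff(I))) == -2) + 1L
  sum(I[loc] > relFloor * max(I))
}
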