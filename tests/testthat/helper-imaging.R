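# Shared imaging fixtures: detection and light-sheet system PSFs, synthetic
# Gaussian spot stacks. Built once per test run.

testDetectionPSF <- local({
  cache <- list()
  function(pitchLat = 0.1) {
    key <- as.character(pitchLat)
    if (!is.null(cache[[key]])) return(cache[[key]])
    psf <- detectionPSF(detectionParams(),
                        pitch = c(pitchLat, pitchLat, 0.2),
                        extent = c(max(1.6, 16 * pitchLat),
                                   max(1.6, 16 * pitchLat), 7.6))
    cache[[key]] <<- psf
    psf
  }
})

# Sheet-narrowed, axially trimmed system PSF (Gaussian sheet, 1/e^2 half
# width sheetW um).
testSystemPSF <- local({
  cache <- list()
  function(pitchLat = 0.1, sheetW = 0.7) {
    key <- paste(pitchLat, sheetW)
    if (!is.null(cache[[key]])) return(cache[[key]])
    det <- testDetectionPSF(pitchLat)
    nz <- dim(det)[3]
    zc <- (seq_len(nz) - (nz + 1) / 2) * voxelPitch(det)[3]
    psf <- trimPSF(systemPSF(exp(-2 * zc^2 / sheetW^2), det))
    cache[[key]] <<- psf
    psf
  }
})

# 3D separable Gaussian spot on a constant background.
gaussianSpotStack <- function(sigma = c(0.15, 0.15, 0.3), peak = 1000,
                              background = 0, dims = c(41, 41, 41),
                              pitch = c(0.1, 0.1, 0.2),
                              center = c(0, 0, 0)) {
  xs <- (seq_len(dims[1]) - (floor(dims[1] / 2) + 1)) * pitch[1] - center[1]
  ys <- (seq_len(dims[2]) - (floor(dims[2] / 2) + 1)) * pitch[2] - center[2]
  zs <- (seq_len(dims[3]) - (floor(dims[3] / 2) + 1)) * pitch[3] - center[3]
  spot <- array(0, dims)
  lat <- exp(-outer(xs^2 / (2 * sigma[1]^2), ys^2 / (2 * sigma[2]^2), "+"))
  for (k in seq_len(dims[3]))
    spot[, , k] <- peak * lat * exp(-zs[k]^2 / (2 * sigma[3]^2))
  imageStack3D(spot + background, pitch)
}

# Dice coefficient between two logical masks.
diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Truth footprint of one scene cell at a phase threshold (noiseless
# geometry: the region whose cytosol chord phase exceeds the threshold).
truthCellFootprint <- function(scene, i, pixelPitch, threshold) {
  dims <- round(scene@fieldSize / pixelPitch)
  xs <- (seq_len(dims[1]) - (floor(dims[1] / 2) + 1)) * pixelPitch
  ys <- (seq_len(dims[2]) - (floor(dims[2] / 2) + 1)) * pixelPitch
  cl <- scene@cells[i, ]
  a <- cl$major / 2; b <- a / cl$aspect; cc <- b
  dx <- xs - cl$x; dy <- ys - cl$y
  co <- cos(cl$orientation); si <- sin(cl$orientation)
  u <- outer(dx, dy * 0, "+") * co + outer(dx * 0, dy, "+") * si
  v <- -outer(dx, dy * 0, "+") * si + outer(dx * 0, dy, "+") * co
  chord <- 2 * cc * sqrt(pmax(1 - (u / a)^2 - (v / b)^2, 0))
  cl$cytosolPhaseScale * chord > threshold
}
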