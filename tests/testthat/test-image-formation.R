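test_that("detection PSF matches the scalar Airy-pattern oracle", {
  psf <- testDetectionPSF(0.05)
  expect_equal(sum(voxels(psf)), 1, tolerance = 1e-12)
  # oracle: first root of [2 J1(v)/v]^2 = 1/2 via besselJ, independent of
  # the pupil-integral implementation
  airyHalf <- function(v) (2 * besselJ(v, 1) / v)^2 - 0.5
  vHalf <- stats::uniroot(airyHalf, c(1, 2))$root
  fwhmOracle <- 2 * vHalf * 0.525 / (2 * pi * 0.7)
  stack <- imageStack3D(voxels(psf) * 1e6, voxelPitch(psf))
  fwhm <- measureFWHM(stack, c(0, 0, 0), "x")
  expect_equal(fwhm, fwhmOracle, tolerance = 0.05)
  expect_equal(fwhmOracle, 0.51 * 0.525 / 0.7, tolerance = 0.02)
})

test_that("halving the NA doubles the lateral FWHM", {
  p1 <- detectionPSF(detectionParams(numericalAperture = 0.7),
                     pitch = c(0.05, 0.05, 0.2), extent = c(1.6, 1.6, 7.6))
  p2 <- detectionPSF(detectionParams(numericalAperture = 0.35),
                     pitch = c(0.05, 0.05, 0.4), extent = c(3.2, 3.2, 30.5))
  f1 <- measureFWHM(imageStack3D(voxels(p1) * 1e6, voxelPitch(p1)),
                    c(0, 0, 0), "x")
  f2 <- measureFWHM(imageStack3D(voxels(p2) * 1e6, voxelPitch(p2)),
                    c(0, 0, 0), "x")
  expect_equal(f2 / f1, 2, tolerance = 0.05)
})

test_that("NA at or above the medium index is rejected", {
  expect_error(detectionParams(numericalAperture = 1.4, mediumIndex = 1.33),
               "smaller than mediumIndex")
})

test_that("sheet profile of a uniform map is constant and bounds are
           checked", {
  img <- matrix(3, 21, 5)
  map <- new("BeamIntensityMap", intensity = img,
             transverseCoords = seq(-2, 2, by = 0.2),
             axialCoords = seq(0, 40, by = 10))
  prof <- sheetAxialProfile(map, 20)
  expect_true(all(prof$intensity == 3))
  expect_error(sheetAxialProfile(map, 50), "outside the map")
})

test_that("sheet profile of a Gaussian focus has 1/e full width sqrt(2) w0", {
  w0 <- 1.2
  map <- scanFocalRegion(gaussianWaistField(w0), 0, 1)
  prof <- sheetAxialProfile(map, 0)
  # interpolated 1/e width via the lobe metrology on the same profile
  width <- mainLobeMetrics(map, 1)$oneOverEDiameter
  expect_equal(width, sqrt(2) * w0, tolerance = 0.01)
  expect_equal(max(prof$intensity), max(intensity(map)))
})

test_that("Airy sheet profile keeps the main lobe and >= 3 side lobes", {
  prof <- sheetAxialProfile(miniAiryLobedMap(), 2e4)
  expect_gte(countLobes(prof$intensity), 4)
})

test_that("system PSF contracts the detection PSF as the sheet narrows", {
  det <- testDetectionPSF(0.1)
  nz <- dim(det)[3]
  # uniform sheet: unchanged
  uni <- systemPSF(rep(2, nz), det)
  expect_equal(voxels(uni), voxels(det), tolerance = 1e-12)
  # one-plane sheet: a single z-slice survives
  delta <- rep(0, nz); delta[(nz + 1) / 2] <- 1
  sl <- systemPSF(delta, det)
  expect_true(all(voxels(sl)[, , -((nz + 1) / 2)] == 0))
  # monotonicity: narrower sheet never increases the axial FWHM
  zc <- (seq_len(nz) - (nz + 1) / 2) * voxelPitch(det)[3]
  widths <- c(4, 2, 1, 0.6)
  fwhms <- vapply(widths, function(w) {
    sp <- systemPSF(exp(-2 * zc^2 / w^2), det)
    measureFWHM(imageStack3D(voxels(sp) * 1e6, voxelPitch(sp)),
                c(0, 0, 0), "z")
  }, numeric(1))
  expect_true(all(diff(fwhms) <= 1e-9))
  expect_error(systemPSF(rep(1, nz - 1), det), "z-planes")
})

test_that("system PSF of an Airy sheet shows side-lobe structure in its
           axial autocorrelation", {
  det <- testDetectionPSF(0.1)
  nz <- dim(det)[3]
  prof <- alignSheetProfile(sheetAxialProfile(miniAiryLobedMap(), 2e4), det)
  sp <- systemPSF(prof, det)
  ax <- apply(voxels(sp), 3, sum)
  ac <- stats::acf(ax, lag.max = nz - 1, plot = FALSE)$acf[, 1, 1]
  # secondary maxima beyond lag 1 reveal the periodic side-lobe spacing
  sec <- which(diff(sign(diff(ac))) == -2) + 1L
  expect_gt(length(sec), 0)
})

test_that("rendering an empty phantom gives the flat background", {
  psf <- testSystemPSF(0.1)
  st <- renderStack(beadPhantom(background = 4), psf, dims = c(16, 16, 17))
  expect_true(all(abs(voxels(st) - 4) < 1e-9))
})

test_that("a sub-voxel bead renders as brightness x PSF at the bead", {
  psf <- testSystemPSF(0.1)
  ph <- beadPhantom(data.frame(x = 0.3, y = -0.2, z = 0.2,
                               diameter = 0.04, brightness = 1e4))
  st <- renderStack(ph, psf, dims = c(32, 32, 21))
  expect_equal(sum(voxels(st)), 1e4, tolerance = 1e-6)
  pk <- which(voxels(st) == max(voxels(st)), arr.ind = TRUE)[1, ]
  ctr <- floor(c(32, 32, 21) / 2) + 1
  pos <- (pk - ctr) * voxelPitch(psf)
  expect_lt(sqrt(sum((pos - c(0.3, -0.2, 0.2))^2)), 0.3)
})

test_that("rendering is linear in brightness and deterministic under a
           seed", {
  psf <- testSystemPSF(0.1)
  mk <- function(b) beadPhantom(data.frame(x = 0, y = 0, z = 0,
                                           diameter = 0.5,
                                           brightness = b),
                                background = 2)
  s1 <- renderStack(mk(1e4), psf, dims = c(24, 24, 17))
  s2 <- renderStack(mk(2e4), psf, dims = c(24, 24, 17))
  expect_equal(voxels(s2) - 2, 2 * (voxels(s1) - 2), tolerance = 1e-9)
  n1 <- renderStack(mk(1e4), psf, dims = c(24, 24, 17), noiseSeed = 5)
  n2 <- renderStack(mk(1e4), psf, dims = c(24, 24, 17), noiseSeed = 5)
  expect_identical(voxels(n1), voxels(n2))
  expect_false(identical(voxels(n1), voxels(s1)))
})

test_that("beads outside the volume are clipped with a warning", {
  psf <- testSystemPSF(0.1)
  ph <- beadPhantom(data.frame(x = c(0, 50), y = 0, z = 0, diameter = 0.5,
                               brightness = 1e3))
  expect_warning(renderStack(ph, psf, dims = c(24, 24, 17)),
                 "outside the volume")
})

test_that("PSF pitch must match the output pitch", {
  psf <- testSystemPSF(0.1)
  expect_error(renderStack(beadPhantom(), psf, dims = c(8, 8, 9),
                           pitch = c(0.2, 0.2, 0.2)), "pitch")
})

test_that("FWHM of a Gaussian spot matches 2 sqrt(2 ln 2) sigma", {
  st <- gaussianSpotStack(sigma = c(0.15, 0.15, 0.3))
  expect_equal(measureFWHM(st, c(0, 0, 0), "z"),
               2 * sqrt(2 * log(2)) * 0.3, tolerance = 0.02)
  expect_equal(measureFWHM(st, c(0, 0, 0), "x"),
               2 * sqrt(2 * log(2)) * 0.15, tolerance = 0.02)
  # off-centre spots are refined from the seed point
  st2 <- gaussianSpotStack(center = c(0.35, -0.21, 0.17))
  expect_equal(measureFWHM(st2, c(0.2, -0.2, 0), "z"),
               2 * sqrt(2 * log(2)) * 0.3, tolerance = 0.03)
})

test_that("degenerate FWHM inputs raise errors", {
  flat <- imageStack3D(array(7, c(9, 9, 9)), c(0.1, 0.1, 0.2))
  expect_error(measureFWHM(flat, c(0, 0, 0), "z"), "no peak")
  # spot too wide for the stack: never drops below half max
  wide <- gaussianSpotStack(sigma = c(1, 1, 10), dims = c(41, 41, 21))
  expect_error(measureFWHM(wide, c(0, 0, 0), "z"), "truncated")
})
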