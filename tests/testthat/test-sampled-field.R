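test_that("source field matches the Gaussian-cubic closed form pointwise", {
  src <- gaussianCubicSource(waist = 4.3, cubicScaling = 5.38)
  fld <- makeSourceField(src, 2^17, 0.25, 0.488)
  x <- fieldCoordinates(fld)
  # pure evaluation: |E| = A exp(-x^2/w0^2), phase = (alpha/3) x^3
  i <- which.min(abs(x - 1000))           # x = 1 mm
  expect_equal(Arg(amplitude(fld)[i]), 5.38 / 3, tolerance = 1e-10)
  expect_equal(abs(5.38 / 3 - 1.7933), 0, tolerance = 1e-4)  # hand value
  i0 <- which.min(abs(x))
  expect_equal(Mod(amplitude(fld)[i0]), 1, tolerance = 1e-12)
  iw <- which.min(abs(x - 4300))          # x = w0
  expect_equal(Mod(amplitude(fld)[iw]), exp(-1), tolerance = 1e-6)
})

test_that("alpha = 0 gives a purely real Gaussian", {
  fld <- makeSourceField(gaussianCubicSource(waist = 4.3), 2^17, 0.25,
                         0.488)
  expect_true(all(Im(amplitude(fld)) == 0))
  expect_true(all(Re(amplitude(fld)) > 0))
})

test_that("undersized grids are rejected with a sizing message", {
  src <- gaussianCubicSource(waist = 4.3)
  expect_error(makeSourceField(src, 2^10, 0.2, 0.488), "grid too small")
  # spans > 3 w0 barely but would clip > 0.1% power? 3 w0 clips ~2e-9,
  # so the clip guard needs a span between the two limits - exercised by
  # the span check itself here.
  expect_silent(makeSourceField(src, 2^17, 0.25, 0.488))
})

test_that("zero-distance propagation is the identity", {
  fld <- gaussianWaistField()
  expect_identical(angularSpectrumPropagate(fld, 0), fld)
})

test_that("negative propagation distances are out of contract", {
  expect_error(angularSpectrumPropagate(gaussianWaistField(), -1),
               "backpropagation")
})

test_that("a plane wave is an eigenfunction: modulus kept, phase k*d", {
  pw <- sampledField(rep(1 + 0i, 256), 0.1, 0.5)
  d <- 3.21
  out <- angularSpectrumPropagate(pw, d)
  expect_equal(Mod(amplitude(out)), rep(1, 256), tolerance = 1e-12)
  expected <- complex(modulus = 1, argument = (2 * pi / 0.5) * d)
  expect_equal(amplitude(out), rep(expected, 256), tolerance = 1e-9)
  expect_equal(axialPosition(out), d)
})

test_that("propagating one Rayleigh range widens a Gaussian by sqrt(2)", {
  w0 <- 1.2
  fld <- gaussianWaistField(w0)
  zr <- pi * w0^2 / 0.488
  out <- angularSpectrumPropagate(fld, zr)
  # 1/e field half-width after z_r is w0 * sqrt(2) (closed form)
  map <- scanFocalRegion(out, 0, 1)
  diam <- mainLobeMetrics(map, 1)$oneOverEDiameter
  # 1/e intensity diameter = sqrt(2) * w(z)
  expect_equal(diam, sqrt(2) * sqrt(2) * w0, tolerance = 0.01)
})

test_that("power over propagating components is conserved to 1e-9", {
  set.seed(11)
  base <- gaussianWaistField(2, 2^11, 0.1)
  # superpose a couple of tilted Gaussians for structure
  x <- fieldCoordinates(base)
  amp <- amplitude(base) + 0.3 * exp(-((x - 20)^2) / 16 + 2i * x) +
    0.1 * exp(-((x + 35)^2) / 9 - 1.2i * x)
  fld <- sampledField(amp, 0.1, 0.488)
  for (d in c(5, 40, 300)) {
    out <- angularSpectrumPropagate(fld, d)
    expect_equal(totalPower(out), totalPower(fld), tolerance = 1e-9)
  }
})

test_that("thin lens is a pure phase element", {
  fld <- gaussianWaistField(2, 2^10, 0.1)
  out <- applyThinLens(fld, 2)
  x <- fieldCoordinates(fld)
  i0 <- which.min(abs(x))
  # T(0) = 1 exactly
  expect_identical(amplitude(out)[i0], amplitude(fld)[i0])
  expect_equal(Mod(amplitude(out)), Mod(amplitude(fld)), tolerance = 1e-14)
  expect_equal(totalPower(out), totalPower(fld), tolerance = 1e-12)
})

test_that("lens multipliers compose: f applied twice equals f/2", {
  fld <- gaussianWaistField(2, 2^10, 0.1)
  twice <- applyThinLens(applyThinLens(fld, 2), 2)
  once <- applyThinLens(fld, 1)
  expect_equal(amplitude(twice), amplitude(once), tolerance = 1e-12)
})

test_that("focusing a collimated Gaussian matches the Fourier-optics form", {
  # low NA so the paraxial closed form applies: w_f = lambda f / (pi w0)
  src <- gaussianCubicSource(waist = 0.3, cubicScaling = 0)
  fld <- makeSourceField(src, 2^15, 0.25, 0.488)
  fld <- propagateTrain(fld, singleLensTrain(2))
  map <- scanFocalRegion(fld, 0, 1, zCenter = 2e4, transverseWindow = 200)
  diam <- mainLobeMetrics(map, 1)$oneOverEDiameter
  wf <- 0.488 * 2e4 / (pi * 300)
  expect_equal(diam, sqrt(2) * wf, tolerance = 0.01)
})

test_that("SampledField validity catches bad grids", {
  expect_error(sampledField(rep(1 + 0i, 3), 0.1, 0.5), "power of two")
  expect_error(sampledField(rep(1 + 0i, 4), -1, 0.5), "gridPitch")
  expect_error(sampledField(rep(1 + 0i, 4), 0.1, 0.5,
                            refractiveIndex = 0.5), "refractiveIndex")
})
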