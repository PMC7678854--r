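test_that("an empty scene is valid and renders to a zero image", {
  sc <- generateCellScene(0, seed = 1)
  expect_equal(nrow(sc@cells), 0L)
  img <- sceneToPhase(sc, 0.2)
  expect_true(all(phaseValues(img) == 0))
  expect_identical(analyzeCells(
    phaseImage(phaseValues(img)[1:60, 1:60], 0.2),
    imageStack3D(array(1, c(60, 60, 4)), c(0.2, 0.2, 0.2)))$cell_id,
    integer(0))
})

test_that("scenes are bit-for-bit reproducible under a fixed seed", {
  s1 <- generateCellScene(6, seed = 99)
  s2 <- generateCellScene(6, seed = 99)
  expect_identical(s1@cells, s2@cells)
  expect_identical(s1@lds, s2@lds)
  expect_identical(s1@truth, s2@truth)
  s3 <- generateCellScene(6, seed = 100)
  expect_false(identical(s1@cells, s3@cells))
  # and the rendered artifacts reproduce too
  f1 <- sceneToFluor(s1, testSystemPSF(0.15), noiseSeed = 5)
  f2 <- sceneToFluor(s2, testSystemPSF(0.15), noiseSeed = 5)
  expect_identical(voxels(f1), voxels(f2))
})

test_that("major axes sample the stated population distribution", {
  sc <- generateCellScene(50, cellSceneParams(fieldSize = c(160, 160)),
                          seed = 12)
  m <- sc@cells$major
  se <- stats::sd(m) / sqrt(50)
  expect_lt(abs(mean(m) - 5.3), 3 * se)
  expect_equal(stats::sd(m), 0.4, tolerance = 0.5)
})

test_that("placement failure in a crowded field is reported", {
  expect_error(generateCellScene(
    40, cellSceneParams(fieldSize = c(20, 20), maxAttempts = 500),
    seed = 1), "enlarge the field")
})

test_that("a sphere projects to chord phase linear in its diameter", {
  params <- cellSceneParams(fieldSize = c(20, 20), aspectRange = c(1, 1),
                            ldCountRange = c(0, 0))
  mk <- function(d) {
    sc <- generateCellScene(1, params, seed = 5)
    sc@cells$major[1] <- d
    sc@cells$x[1] <- 0; sc@cells$y[1] <- 0
    sc@cells$cytosolPhaseScale[1] <- 0.35
    max(phaseValues(sceneToPhase(sc, 0.05)))
  }
  p4 <- mk(4); p2 <- mk(2)
  expect_equal(p4, 0.35 * 4, tolerance = 0.01)
  expect_equal(p4 / p2, 2, tolerance = 0.01)
})

test_that("projected phase mass matches the scene's analytic dry mass", {
  sc <- generateCellScene(4, cellSceneParams(fieldSize = c(30, 30)),
                          seed = 8)
  img <- sceneToPhase(sc, 0.05)
  p <- dryDensityParams()
  mass <- sum(dryDensity(phaseValues(img), p)) * 0.05^2
  expect_equal(mass, sum(sc@truth$dryMass), tolerance = 0.02)
})

test_that("diffusive flux fills the cell volume as geometry predicts", {
  params <- cellSceneParams(fieldSize = c(14, 14), ldCountRange = c(1, 1),
                            localizedFraction = 0)   # all diffusive
  sc <- generateCellScene(1, params, seed = 21)
  fl <- sceneToFluor(sc, testSystemPSF(0.1), zExtent = 6, background = 0)
  truth <- attr(fl, "truthDensity")
  ld <- sc@lds[1, ]; cl <- sc@cells[1, ]
  ctr <- c(cl$x + ld$dx, cl$y + ld$dy, 0)
  dist <- sqrt(outer(outer(
    ((seq_len(dim(truth)[1]) - (floor(dim(truth)[1] / 2) + 1)) * 0.1 -
       ctr[1])^2,
    ((seq_len(dim(truth)[2]) - (floor(dim(truth)[2] / 2) + 1)) * 0.1 -
       ctr[2])^2, "+"),
    ((seq_len(dim(truth)[3]) - (floor(dim(truth)[3] / 2) + 1)) * 0.2)^2,
    "+"))
  shell <- abs(dist - ld$diameter / 2) <= 0.3
  shellFrac <- sum(truth[shell]) / sum(truth)
  # geometric oracle: shell volume / cell volume
  a <- cl$major / 2; b <- a / cl$aspect
  vShell <- sum(shell) * prod(c(0.1, 0.1, 0.2))
  # the shell protrudes partly outside the cell; bound the comparison
  vCell <- 4 / 3 * pi * a * b * b
  expect_equal(shellFrac, vShell / vCell, tolerance = 0.1)
  expect_lt(shellFrac, 0.5)
})

test_that("localized flux recovers the set coverage after blurring", {
  params <- cellSceneParams(fieldSize = c(14, 14), ldCountRange = c(1, 1),
                            localizedFraction = 1,
                            coverageRange = c(0.5, 0.5))
  psf <- testSystemPSF(0.1)
  covs <- vapply(1:4, function(s) {
    sc <- generateCellScene(1, params, seed = s)
    fl <- sceneToFluor(sc, psf, zExtent = 6, background = 2, noiseSeed = s)
    ld <- sc@lds[1, ]; cl <- sc@cells[1, ]
    thr <- 2 + 0.5 * (max(voxels(fl)) - 2)
    ldSurfaceCoverage(fl, c(cl$x + ld$dx, cl$y + ld$dy, 0), ld$diameter,
                      contactDistance = 0.2, intensityThreshold = thr)
  }, numeric(1))
  expect_lt(abs(mean(covs) - 50), 10)
})

test_that("zero expression renders a background-only stack", {
  params <- cellSceneParams(fieldSize = c(14, 14), expressionMean = 0,
                            expressionSd = 0, ldCountRange = c(0, 0))
  sc <- generateCellScene(2, params, seed = 3)
  sc@truth$expression <- 0
  fl <- sceneToFluor(sc, testSystemPSF(0.1), zExtent = 6, background = 7)
  expect_true(all(abs(voxels(fl) - 7) < 1e-9))
})

## Four-bucket QPI forward model and reconstruction

test_that("zero phase reconstructs to exactly zero", {
  rt <- qpiForwardAndReconstruct(phaseImage(matrix(0, 16, 16), 0.1))
  expect_true(all(phaseValues(rt$reconstructed) == 0))
  expect_length(rt$frames, 4L)
})

test_that("a uniform weak phase offset round-trips within 1%", {
  for (phi0 in c(0.2, 0.6, 1)) {
    img <- phaseImage(matrix(phi0, 12, 12), 0.1)
    rec <- phaseValues(qpiForwardAndReconstruct(img)$reconstructed)
    expect_lt(max(abs(rec - phi0)) / phi0, 0.01)
  }
})

test_that("a cell phase map round-trips with Dice >= 0.95 at thresholds", {
  sc <- generateCellScene(3, cellSceneParams(fieldSize = c(24, 24)),
                          seed = 17)
  img <- sceneToPhase(sc, 0.1)
  rec <- qpiForwardAndReconstruct(img)$reconstructed
  expect_lt(max(abs(phaseValues(rec) - phaseValues(img))), 0.02)
  for (thr in c(0.5, 1.45)) {
    m1 <- phaseValues(img) > thr
    m2 <- phaseValues(rec) > thr
    if (sum(m1)) expect_gte(diceCoef(m1, m2), 0.95)
  }
})

test_that("the shift list must be the quarter-wave sequence", {
  img <- phaseImage(matrix(0.1, 4, 4), 0.1)
  expect_error(qpiForwardAndReconstruct(img, shifts = c(0, pi)), "four")
  expect_error(qpiForwardAndReconstruct(img,
                                        shifts = c(0.3, 1, 2, 3)),
               "quarter-wave")
})
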