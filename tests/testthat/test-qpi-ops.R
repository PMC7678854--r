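test_that("dry density evaluates the phase-mass relation exactly", {
  p <- dryDensityParams()   # 0.5 um, 1.85e-4 m^3/kg
  expect_equal(dryDensity(0, p), 0)
  # hand evaluation: 5e-7 m / (2 pi 1.85e-4 m^3/kg) = 4.302e-4 kg/m^2
  handKgM2 <- 5e-7 / (2 * pi * 1.85e-4)
  expect_equal(dryDensity(1, p), handKgM2 * 1e3, tolerance = 1e-12)
  expect_equal(dryDensity(1, p), 0.430, tolerance = 1e-3)
  # exact linearity
  expect_identical(dryDensity(2 * 0.7, p), 2 * dryDensity(0.7, p))
  phis <- c(0.1, 0.5, 2, 10)
  expect_equal(dryDensity(phis, p), phis * dryDensity(1, p))
})

test_that("expression level is the background-subtracted cell mean", {
  vox <- array(100, c(10, 10, 5))
  cell <- matrix(FALSE, 10, 10); cell[3:6, 3:6] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[9:10, ] <- TRUE
  vox[3:6, 3:6, ] <- 150
  st <- imageStack3D(vox, c(0.1, 0.1, 0.2))
  expect_equal(as.numeric(expressionLevel(st, cell, bg)), 50)
  # uniform stack -> exactly zero
  uni <- imageStack3D(array(42, c(10, 10, 5)), c(0.1, 0.1, 0.2))
  expect_equal(as.numeric(expressionLevel(uni, cell, bg)), 0)
  # offset invariance
  st2 <- imageStack3D(vox + 17, c(0.1, 0.1, 0.2))
  expect_equal(as.numeric(expressionLevel(st2, cell, bg)), 50)
  # negative results are flagged, not clipped
  vox3 <- vox; vox3[3:6, 3:6, ] <- 60
  neg <- expressionLevel(imageStack3D(vox3, c(0.1, 0.1, 0.2)), cell, bg)
  expect_equal(as.numeric(neg), -40)
  expect_true(attr(neg, "negative"))
  expect_error(expressionLevel(st, matrix(FALSE, 10, 10), bg), "empty cell")
})

# Build a stack with flux on (part of) a droplet-surface shell plus
# uniform cytosol, on a known geometry.
shellStack <- function(dims = c(40, 40, 30), pitch = c(0.1, 0.1, 0.2),
                       r = 0.6, capCos = -1, shellFlux = 900,
                       cytosolFlux = 0, background = 0) {
  xs <- (seq_len(dims[1]) - (floor(dims[1] / 2) + 1)) * pitch[1]
  ys <- (seq_len(dims[2]) - (floor(dims[2] / 2) + 1)) * pitch[2]
  zs <- (seq_len(dims[3]) - (floor(dims[3] / 2) + 1)) * pitch[3]
  vox <- array(background, dims)
  for (k in seq_along(zs)) {
    dist <- sqrt(outer(xs^2, ys^2, "+") + zs[k]^2)
    shell <- abs(dist - r) <= 0.12
    # cap: polar angle measured from +z axis; capCos = cos(theta_max)
    ca <- zs[k] / pmax(dist, 1e-9)
    vox[, , k][shell & ca >= capCos] <- shellFlux
    if (cytosolFlux > 0) {
      cell <- dist <= 2.2
      vox[, , k][cell & !shell] <- cytosolFlux
    }
  }
  imageStack3D(vox, pitch)
}

test_that("flux concentrated on the droplet shell classifies as localized", {
  st <- shellStack(shellFlux = 900, cytosolFlux = 2, background = 1)
  expect_equal(classifyLocalization(st, c(0, 0, 0), 1.2, background = 1),
               "localized")
})

test_that("uniform cytosolic flux classifies as diffusive", {
  # 5.3 um cell with a 1 um droplet: the shell holds a tiny volume share
  dims <- c(60, 60, 30); pitch <- c(0.1, 0.1, 0.2)
  xs <- (seq_len(dims[1]) - 31) * 0.1
  zs <- (seq_len(dims[3]) - 16) * 0.2
  vox <- array(0, dims)
  for (k in seq_along(zs)) {
    lat <- outer((xs / 2.65)^2, (xs / 1.9)^2, "+")
    vox[, , k][lat + (zs[k] / 1.9)^2 <= 1] <- 50
  }
  st <- imageStack3D(vox, pitch)
  expect_equal(classifyLocalization(st, c(0.5, 0, 0), 1, background = 0),
               "diffusive")
})

test_that("without a droplet the call is diffusive by contract", {
  st <- shellStack()
  expect_equal(classifyLocalization(st, NULL, 1), "diffusive")
})

test_that("surface coverage hits the 0%/100% extremes", {
  quiet <- imageStack3D(array(1, c(30, 30, 24)), c(0.1, 0.1, 0.2))
  expect_equal(ldSurfaceCoverage(quiet, c(0, 0, 0), 1.0,
                                 intensityThreshold = 5), 0)
  full <- shellStack(capCos = -1)
  expect_equal(ldSurfaceCoverage(full, c(0, 0, 0), 1.2,
                                 intensityThreshold = 100), 100)
})

test_that("a hemispherical cap covers ~50% of the droplet surface", {
  hemi <- shellStack(dims = c(50, 50, 36), r = 1.2, capCos = 0)
  cov <- ldSurfaceCoverage(hemi, c(0, 0, 0), 2.4,
                           contactDistance = 0.205,
                           intensityThreshold = 100)
  # brute-force oracle over the same generated geometry: enumerate the
  # sphere's surface voxels and check each for a supra-threshold voxel
  # within the contact distance, with plain loops
  pitch <- c(0.1, 0.1, 0.2); dims <- c(50, 50, 36); r <- 1.2
  ax <- lapply(1:3, function(i)
    (seq_len(dims[i]) - (floor(dims[i] / 2) + 1)) * pitch[i])
  dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
  sphere <- dist <= r
  surf <- which(sphere, arr.ind = TRUE)
  inner <- apply(surf, 1, function(v) {
    for (d in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[d] <- w[d] + s
      if (any(w < 1) || any(w > dims) || !sphere[w[1], w[2], w[3]])
        return(FALSE)
    }
    TRUE
  })
  surf <- surf[!inner, , drop = FALSE]
  supra <- which(voxels(hemi) > 100, arr.ind = TRUE)
  supraPos <- cbind(ax[[1]][supra[, 1]], ax[[2]][supra[, 2]],
                    ax[[3]][supra[, 3]])
  covered <- vapply(seq_len(nrow(surf)), function(i) {
    p <- c(ax[[1]][surf[i, 1]], ax[[2]][surf[i, 2]], ax[[3]][surf[i, 3]])
    any(sqrt(colSums((t(supraPos) - p)^2)) <= 0.205)
  }, logical(1))
  oracle <- 100 * mean(covered)
  expect_equal(cov, oracle, tolerance = 1e-9)
  # one discretization ring (z pitch + contact reach) around the equator
  quantum <- 100 * (pitch[3] + 0.205) / (2 * r)
  expect_lt(abs(cov - 50), quantum + 2)
})

test_that("coverage is monotone in the true cap fraction", {
  fractions <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  covs <- vapply(fractions, function(f) {
    st <- shellStack(capCos = 1 - 2 * f)
    ldSurfaceCoverage(st, c(0, 0, 0), 1.2, contactDistance = 0.2,
                      intensityThreshold = 100)
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("coverage guards its geometric preconditions", {
  st <- shellStack()
  expect_error(ldSurfaceCoverage(st, c(0, 0, 0), 1.2,
                                 contactDistance = 0.05,
                                 intensityThreshold = 1),
               "largest voxel pitch")
  expect_error(ldSurfaceCoverage(st, c(3, 0, 0), 3,
                                 intensityThreshold = 1),
               "outside the volume")
})
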