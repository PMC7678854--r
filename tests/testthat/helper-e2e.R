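# End-to-end fixture: one rendered scene analysed by the full chain.
analyzeScene <- function(seed, nCells = 2, fieldSize = c(15, 15),
                         params = list(), rlIterations = 8,
                         phaseSNR = 20) {
  p <- do.call(cellSceneParams,
               c(list(fieldSize = fieldSize, ldCountRange = c(1, 1)),
                 params))
  sc <- generateCellScene(nCells, p, seed = seed)
  psf <- testSystemPSF(0.15)
  ph <- sceneToPhase(sc, 0.15, noiseSd = p$peakCytosolPhase / phaseSNR,
                     noiseSeed = seed)
  fl <- sceneToFluor(sc, psf, zExtent = 6, background = 5,
                     noiseSeed = seed)
  if (rlIterations > 0)
    fl <- richardsonLucy(fl, psf, deconvolutionSettings(rlIterations))
  rec <- analyzeCells(ph, fl, analysisConfig(
    coverageThresholdFactor = 0.5, contactDistance = 0.2))
  idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((sc@cells$x - rec$x_um[i])^2 +
                (sc@cells$y - rec$y_um[i])^2), integer(1))
  list(scene = sc, records = rec, match = idx)
}

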