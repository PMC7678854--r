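# AiryQPI

Computational core of an integrative imaging workflow that pairs
quantitative-phase imaging (QPI) with an Airy-beam light sheet on one
microscope: simulate the illumination optics, form and deconvolve 3D
light-sheet stacks, and run the label-free per-cell analysis — all
verifiable end-to-end on ground-truthed synthetic phantoms.

It is aimed at microscopists and image-analysis developers who want the
numerical half of such a system without the instrument: to size an
illumination design, to test segmentation/coverage estimators against
known truth, or to reproduce the processing chain on their own stacks.

The package has four parts:

* **Beam simulator** — angular-spectrum (FFT-BPM) propagation of a
  cubic-phase Gaussian source, `E0 = A exp(-x²/w0²) exp(i α x³/3)`,
  through a thin-lens train (`exp(-i (2π/λ) x²/2f)` per lens), with
  main-lobe metrology: tracked 1/e intensity diameter, parabolic
  self-bending trajectory, and the diffraction-free length (longest
  axial run with diameter ≤ √2 × its minimum). The default train is the
  seven-lens illumination path (75.6, 40, 3.5, 1.2, 7.5, 30 cm and a
  2 cm objective) at λ = 0.488 µm, w0 = 4.3 mm, α = 5.38 mm⁻³.
* **Image formation** — scalar-diffraction detection PSF (NA 0.7,
  emission 0.525 µm), light-sheet system PSF (detection PSF windowed in
  z by the sheet profile), bead-phantom rendering with Poisson noise,
  FWHM metrology, and Richardson–Lucy 3D deconvolution.
* **QPI analysis** — phase-threshold segmentation (8-connectivity,
  hole filling), dry-mass surface density
  `ρ = λ⟨Φ⟩/(2π·dn/dc)` (0.430 pg/µm² per radian at λ = 0.5 µm,
  dn/dc = 1.85×10⁻⁴ m³/kg), background-subtracted expression,
  lipid-droplet localization calls, % droplet-surface coverage, and a
  Mann–Whitney U test with exact two-sided p values.
* **Phantoms** — seeded generators for bead fields and yeast-like cell
  scenes (5.3 ± 0.4 µm ellipsoids with higher-phase droplets,
  localized or diffusive fluorophores), plus a four-bucket
  phase-shifting QPI forward model and reconstruction.

## Worked example

Simulate a small cubic-phase beam brought to focus by one lens and
measure it:

```r
library(AiryQPI)

src   <- gaussianCubicSource(waist = 0.5, cubicScaling = 20)  # mm, mm^-3
field <- makeSourceField(src, gridSize = 2^14, gridPitch = 0.2,
                         wavelength = 0.488)
field <- propagateTrain(field, opticalTrain(list(
  list(type = "gap",  d_cm = 1),
  list(type = "lens", f_cm = 1))))
map <- scanFocalRegion(field, zWindow = 400, axialPitch = 2,
                       zCenter = 1e4, transverseWindow = 160)
head(beamMetrics(map), 3)
#>    z_um lobe_center_um diameter_um     peak
#> 1 19800      -2.116900    12.34194 57.60385
#> 2 19802      -2.055838    12.16961 58.40336
#> 3 19804      -1.995120    11.99322 59.21426
diffractionFreeLength(map)
#> [1] 246
```

The tracked main lobe narrows to ~5–8 µm (1/e intensity) through the
focal corridor and stays within √2 of its narrowest width over 246 µm; its centre drifts
parabolically (self-acceleration). A Gaussian reference
(`gaussianWaistModel(1.2, 0.488)`) is diffraction-free over only
2·z_r ≈ 18.5 µm under the same criterion.

Generate a ground-truthed cell scene and analyse it end-to-end:

```r
scene <- generateCellScene(2, cellSceneParams(fieldSize = c(15, 15),
                                              ldCountRange = c(1, 1)),
                           seed = 42)
phase <- sceneToPhase(scene, 0.15, noiseSd = 1.3 / 20, noiseSeed = 42)

det   <- detectionPSF(detectionParams(), pitch = c(0.15, 0.15, 0.2),
                      extent = c(1.8, 1.8, 7.6))
zc    <- (seq_len(dim(det)[3]) - (dim(det)[3] + 1) / 2) * 0.2
psf   <- trimPSF(systemPSF(exp(-2 * zc^2 / 0.7^2), det))  # 0.7 um sheet
fluor <- sceneToFluor(scene, psf, zExtent = 6, background = 5,
                      noiseSeed = 42)
fluor <- richardsonLucy(fluor, psf, deconvolutionSettings(8))

analyzeCells(phase, fluor,
             analysisConfig(coverageThresholdFactor = 0.5,
                            contactDistance = 0.2))
#>   cell_id      x_um      y_um area_um2 mean_phase_rad dry_density_pg_um2
#> 1       1 -1.530000  2.366143  15.7500       1.000902          0.4305365
#> 2       2  3.375126 -1.892327  13.3425       1.051454          0.4522815
#>   erg6_expr localization ld_diam_um coverage_pct
#> 1  22.23645    localized   1.220529     61.29032
#> 2  44.02584    diffusive   1.494836     91.57303
```

One row per interior cell: area and mean phase from the segmented
mask, dry density from the phase (pg/µm²), background-subtracted
expression, the droplet-localization call, the droplet's
equivalent-area diameter, and the percent of its surface in contact
with fluorescence. For this seed the ground truth is: cell 1 a
localized fluorophore with 43% set coverage and expression 77, cell 2
truly diffusive with expression 160 - the localization calls are
correct, the expression ordering is preserved, and the diffusive
cell's cytosolic fluorescence surrounds its droplet, so its high
coverage is the expected reading. `mannWhitney()` compares groups of
such records with exact p values.

A thin CLI wraps the same functions
(`inst/cli/airysheet simulate-beam|build-psf|render-stack|deconvolve|analyze|phantom|measure-fwhm`);
every run writes a JSON manifest echoing its resolved configuration
and seed.

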