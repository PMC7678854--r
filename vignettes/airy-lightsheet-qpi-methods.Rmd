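---
title: "Methods: Airy light-sheet simulation and quantitative-phase cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Airy light-sheet simulation and quantitative-phase cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(AiryQPI)
```

AiryQPI implements the computational core of an integrative imaging
workflow that combines quantitative-phase imaging (QPI) with an
Airy-beam light sheet: a scalar beam-propagation simulator of the
illumination train, a light-sheet image-formation and deconvolution
stage, and the per-cell QPI analysis (dry-mass density, expression,
lipid-droplet surface statistics). Every stage can be exercised on
ground-truthed synthetic phantoms, so the whole chain is testable
without access to a microscope. This vignette explains the models, their
assumptions, the defaults, and what the synthetic tests do and do not
demonstrate about real data.

## Beam propagation model

A monochromatic scalar field `E(x, z)` obeying the Helmholtz equation is
advanced by the angular-spectrum method (FFT-BPM): the field's Fourier
spectrum is multiplied by `exp(i k_z d)` with
`k_z = sqrt(k^2 - k_x^2)`, `k = 2 pi n / lambda`. Evanescent components
(`k_x^2 > k^2`) are set to zero rather than exponentially damped: all
propagation distances here are macroscopic, so those components are
irrelevant and zeroing them is the simplest contract that keeps the
power bookkeeping exact. Power over the propagating band is conserved
to better than 1e-9 (FFT round-off only).

The model is two-dimensional - one transverse axis plus the propagation
axis. For a separable cubic mask (the phase is a sum of per-axis cubic
terms) paraxial propagation factorizes, so the 1D transverse profile is
exactly the per-axis behaviour of the full beam; the 2D restriction is
what makes a 2^20-point grid affordable.

The source is a Gaussian illuminating a cubic phase mask,
`E0(x) = A exp(-x^2/w0^2) exp(i alpha x^3 / 3)`, specified in bench
units (mm, mm^-3) and sampled in um. Defaults: `A = 1`, `w0 = 4.3` mm,
`alpha = 5.38` mm^-3, `lambda = 0.488` um, `n = 1`. Thin lenses
multiply by `exp(-i (2 pi / lambda) x^2 / 2 f)` - a pure phase; the
default train is the seven-lens illumination path (75.6, 40, 3.5, 1.2,
7.5, 30 cm relays and the illumination objective modelled as a 2 cm
thin lens) with the cascaded-4f gap layout: the source sits one focal
length before the first lens and consecutive lenses are separated by
the sum of their focal lengths. Each relay therefore images the mask
onto the next plane and the final lens Fourier-transforms the relayed
mask into its focal region, producing the finite-energy Airy profile.

Two numerical points deserve mention:

* **Exact versus paraxial.** The angular-spectrum kernel is exact while
  the thin-lens phase is quadratic (paraxial). At the final pupil
  (relayed beam waist ~3.1 mm, f = 2 cm, NA ~ 0.16) the difference is
  a real spherical-aberration-like term that shifts and broadens the
  focus relative to textbook Gaussian formulas by a few percent. The
  closed-form oracles (Gaussian waist law, `w_f = lambda f / (pi w0)`
  focusing) are therefore checked in low-NA configurations where the
  paraxial form is valid to better than 1%, and the `alpha -> 0` limit
  is checked as limit *continuity* (a tiny-alpha run must agree with
  the alpha = 0 run to 1e-6 in intensity), not as 1e-6 agreement with
  a paraxial formula that the exact model intentionally does not
  reproduce.
* **Sampling validity.** Advancing a stored spectrum by a distance d is
  valid while the spectral phase stays Nyquist-sampled over the band
  the field occupies; `scanFocalRegion()` estimates that band and warns
  when a window stretches past it.

### Beam metrology

`beamMetrics()` tracks the main lobe across axial planes: the first
plane uses the global intensity maximum, later planes the maximum
within a 10 um search window around the previous centre
(nearest-lobe continuity, so the tracker does not hop onto Airy side
lobes), with three-point parabolic sub-sample refinement. The beam
diameter is the full width at intensity = peak/e around the tracked
lobe, linearly interpolated between samples; intensity (not field)
1/e is the default reading of "1/e beam diameter". The
diffraction-free length is the longest contiguous axial interval over
which that diameter stays within sqrt(2) of its minimum over the map -
the sqrt(2) factor is this package's criterion, chosen as the
Gaussian-confocal analogue (a Gaussian beam is then diffraction-free
over exactly two Rayleigh ranges, `2 z_r = 2 pi w0^2 n / lambda`),
since no explicit width criterion accompanies the published figure.

Under the default parameters the simulated Airy corridor is much longer
than the 200 x 200 um^2 field of view the instrument images: the main
lobe (~7 um 1/e width) stays within the sqrt(2) band for well over a
millimetre around the final focus, and a 400 um measurement window
therefore saturates - the measured diffraction-free length equals the
window length. The ~200 um path reported for the physical instrument is
bounded by its observable field, not by the beam model; we report what
the stated model computes and do not calibrate `alpha` to shrink the
corridor. (A related published inconsistency: a +-84 pi mask excursion
over 10 mm does not follow from `alpha x^3 / 3` with
`alpha = 5.38 mm^-3`, which gives +-71 pi; `alpha` is exposed directly
and the +-84 pi figure is not enforced.)

Default sampling is `2^20` points at 0.2 um transverse pitch with a
0.2 um axial step over a 4 mm window, all configurable; the acceptance
computations coarsen the axial step to 1-2 um, justified by the
grid-robustness property (halving/doubling the sampling moves the
diffraction-free length by under 2%).

## Image formation

The detection PSF is the scalar paraxial pupil integral for a circular
pupil (Gauss-Legendre quadrature on the radial integral, 128 nodes),
evaluated on an (r, z) polar grid and interpolated onto voxels; it is
normalized to unit sum. Scalar rather than vectorial diffraction is a
deliberate simplification - at NA 0.7 it is accurate enough for testing
geometry and resolution bookkeeping, which is all the package needs.
Defaults: NA 0.7, emission 0.525 um (bandpass centre), medium index
1.33.

Light-sheet image formation multiplies the detection PSF along z by
the illumination sheet profile (the beam's transverse profile at the
chosen propagation distance; scanning is modelled as uniform) and
renormalizes. A sheet narrower than the detection PSF tightens the
system PSF axially; an Airy sheet imprints its side-lobe structure,
which is what Richardson-Lucy deconvolution subsequently removes.

Bead phantoms are rasterized by 4x sub-voxel volume sampling
(box-averaged); beads at or below half a voxel are deposited as
trilinear deltas. Expected counts are truth convolved with the PSF
plus a constant background; Poisson noise is applied only under an
explicit seed, so noiseless expectations and reproducible noisy stacks
are both available. FWHM metrology refines the local maximum near a
seed point, subtracts the border-median background, parabolically
refines the peak height and interpolates the half-maximum crossings;
profiles that never fall below half maximum raise a "truncated spot"
error rather than returning a guess. At low signal-to-noise the
walk-out to the half-maximum crossing can stop early on a noise dip;
resolution claims are therefore always made at SNR >= 20.

## Richardson-Lucy deconvolution

The standard multiplicative update
`e <- e * ((d / (e * h)) * h~)` with the flipped kernel `h~`,
FFT convolutions, reflective padding by one PSF half-extent (padded up
to FFT-friendly sizes), a 1e-12 guard on the division, and a fixed
iteration count (default 50; no automatic stopping rule, the simplest
reproducible contract - the published processing did not state one).
The iterate stays non-negative, conserves total intensity to within
0.1% per run with a unit-sum PSF, and monotonically increases the
Poisson data log-likelihood (`poissonLogLik()` exposes the objective
for monitoring).

## QPI analysis

Segmentation is direct phase thresholding: 8-connected components of
`phase > threshold`, holes filled, small regions discarded, ordered by
area, cells touching the border excluded. Droplets are segmented the
same way at a higher threshold and assigned to the cell containing the
majority of their pixels. The thresholds are assay parameters (the
published workflow thresholds "at different levels" without numbers);
the defaults (0.5 rad cell, 1.45 rad droplet) match the phantom
generator's phase scale.

Dry-mass surface density converts mean phase by
`rho = lambda <Phi> / (2 pi dn/dc)` with `lambda = 0.5` um and
`dn/dc = 1.85e-4 m^3 kg^-1`; with those units
`1 rad -> 0.430 pg um^-2` (`1 kg m^-2 = 1000 pg um^-2`). Expression is
the cell's mean fluorescence minus the extracellular mean; negative
values are flagged, not clipped.

The droplet's 3D position is estimated from its 2D mask: sphere at the
mask centroid with the equivalent-area diameter, z at the plane of
maximal in-mask fluorescence. Localization is called "localized" when
more than half of the cell's above-background flux falls within a
spherical shell of +-0.3 um around the droplet surface; in
`analyzeCells()` "above background" means above the extracellular
median plus two extracellular standard deviations, so Poisson
background fluctuations do not flood the denominator. Surface coverage
discretizes the sphere surface into its surface voxels and counts the
fraction with a supra-threshold fluorescence voxel within the contact
distance. The contact distance defaults to one voxel diagonal in the
standalone operation; with anisotropic voxels the end-to-end analysis
uses the minimum the estimator permits (the largest voxel pitch), which
keeps the dilation of the covered region as small as the grid allows.
The coverage intensity threshold is half of the background-subtracted
cell maximum - an FWHM-style cut that is symmetric under blurring.
No multiple-testing correction is applied to group comparisons (raw
rank-test p values are reported).

`mannWhitney()` computes U from midranks; for `n1 * n2 <= 400` the
two-sided p value is exact, from the full permutation distribution of
the rank sum (computed by the count-generating dynamic programme over
the observed midranks, which enumerates exactly the
`choose(n1 + n2, n1)` labelings), `p = min(1, 2 min(P(U <= u),
P(U >= u)))`; larger problems use the normal approximation with
tie-corrected variance and continuity correction.

## Synthetic phantoms

`generateCellScene()` emulates a sedimented yeast monolayer: prolate
ellipsoids lying flat, major axis ~ Normal(5.3, 0.4) um, in-plane
aspect ratio U(1.2, 1.6), placed without overlap by rejection sampling.
Phase is the chord length through the cell times a per-cell scale
chosen so every cell peaks at the same cytosol phase (1.3 rad by
default) - constant volumetric density, which is also what makes one
global threshold meaningful across a population; droplets add excess
chord phase (0.6 rad/um). The per-cell dry mass is recorded
analytically, so the projected phase image can be checked against the
truth to 2%.

Fluorophore truth per cell: an expression level (Normal(120, 30),
shifted up by one standard deviation for droplet-localized cells - the
study condition that high expressors tend to be localized), a
localized/diffusive mode, and for localized cells a set coverage
fraction U(0.2, 0.8). Diffusive flux fills the cell volume uniformly;
localized flux sits on a spherical cap of the droplet surface whose
area fraction equals the set coverage, around a seeded random axis.
Total flux is scaled to the cell's footprint column so that the
background-subtracted mean intensity tracks the expression level
itself, independent of cell size - the same quantity the analysis
measures. Droplet counts per cell default to 0-2 (no published
distribution exists; it is a free parameter, as are the expression and
droplet-size distributions).

The four-bucket QPI model treats the un-scattered reference as a unit
plane wave and the scattered field as `exp(i phi) - 1`; the four
interferograms at reference steps pi/2, pi, 3pi/2, 2pi are inverted by
the standard phase-shifting arctangent estimator (the reconstruction
formula is standard interferometry, not a contribution of this
package). The inversion is exact up to phase wrapping at +-pi, so the
round-trip requirement (<1% for peak phase <= 1 rad) is met with large
margin.

What the phantoms do *not* emulate: optical-path aberrations, coherent
speckle and halo artefacts of real QPI reconstructions, organelle
ultrastructure beyond one droplet sphere per cell, autofluorescence,
camera read noise, or cell motion. Passing the end-to-end tests shows
the estimators are consistent with their own forward models at
realistic geometry, pitch and noise - not that the thresholds would
transfer to a particular instrument without recalibration.

## End-to-end verification conditions

The recovery suite runs 200 seeded scenes of two cells each in a
14 x 14 um field at (0.15, 0.15, 0.2) um voxel pitch, phase SNR 20,
Poisson fluorescence noise over background 5, the sheet-narrowed
(0.7 um) system PSF trimmed to its significant z-planes, and 8
Richardson-Lucy iterations before analysis - scaled so the suite runs
in minutes while leaving every estimator's error regime unchanged. It
asserts: exact per-scene cell counts; mean segmentation Dice >= 0.9
against the generator's noiseless footprints; >= 95% correct
localization labels; and population-mean coverage recovery within 10
percentage points. Coverage is a population-level statement
deliberately: for ~1 um droplets at 0.15-0.2 um voxels, single-cell
coverage estimates carry an irreducible discretization-plus-blur
scatter of roughly +-15-20 percentage points, which averages out but
cannot be asserted per cell.

## Known limitations

* The beam model is scalar, 2D and thin-lens; pupil apodization,
  aberrations and SLM quantization are out of scope.
* The coverage estimator is positively biased when the point-spread
  blur or the contact distance is comparable to the droplet radius;
  deconvolution and the half-maximum cut reduce but do not remove the
  bias.
* The droplet z-position estimator (plane of maximal in-mask
  fluorescence) is biased toward the fluorescent cap for strongly
  localized cells; this is the dominant single-cell coverage error
  source.
* TIFF float pages are stored normalized with the scale and voxel
  pitch in a JSON sidecar, because the available writer clamps float
  samples to [0, 1] and cannot write description tags.
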