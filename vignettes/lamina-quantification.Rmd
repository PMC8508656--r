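---
title: "Quantifying nuclear lamina thickness and lamin colocalization"
author: "laminq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear lamina thickness and lamin colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The nuclear lamina is a filamentous meshwork of A- and B-type lamins lining
the inner nuclear membrane.  Its physical thickness is on the order of
14 nm — far below the resolution of any light microscope.  Two quantities
are nevertheless routinely extracted from confocal (CSLM, effective
resolution ~241 nm here) and STED (~60 nm) images of lamin-stained nuclei:

1. **Apparent layer thickness.**  At the nuclear mid-plane the lamina
   appears as a bright rim.  An intensity profile sampled perpendicular to
   the rim is fitted with a Gaussian, and the layer thickness is reported
   as the full width at half maximum, FWHM = 2√(2 ln 2)·σ ≈ 2.3548·σ.
   Because the true shell is much thinner than the point spread function
   (PSF), this FWHM is effectively a measure of the *optical resolution*,
   not of the shell itself; the smallest FWHM observed across a dataset is
   the conventional effective-resolution statistic.
2. **Lamin A/C–lamin B1 colocalization.**  At the top of the nucleus the
   lamina appears as a meshwork.  The two channels' pixel intensities are
   correlated with Pearson's coefficient after Costes automatic
   thresholding, which removes background pixels by lowering thresholds
   along the inter-channel regression line until the sub-threshold pixels
   show no positive correlation.

Since raw microscopy data for this kind of study are typically not
deposited, laminq ships a **ground-truthed simulator** so that every stage
of the pipeline — rim segmentation, profile fitting, deconvolution,
thresholding, statistics — can be validated against a known answer.

## The synthetic scene model

`scene_config()` + `build_lamina_scene()` produce a noiseless,
supersampled (default 5 nm/cell) two-channel scene:

* **Mid-plane view**: an elliptical shell of radial width
  `true_thickness_nm` (default 14 nm) centred on the rim of an ellipse
  (default semi-axes 2.2 × 1.7 µm — deliberately smaller than a real
  fibroblast nucleus; thickness and colocalization are local properties of
  the rim, so the package's results do not depend on nucleus size, and the
  smaller field keeps simulations cheap), over a diffuse nucleoplasmic
  interior at `nucleoplasm_level` (default 0.02 of the unblurred shell
  intensity; at this level the blurred rim remains the brightest structure
  under both modalities, matching the appearance of published mid-plane
  profiles).
* **Top view**: random straight filament segments of width
  `true_thickness_nm` in a 5 µm field (mesh density 6 filaments/µm², mean
  length 1.2 µm).  A fraction ρ = `shared_fraction` of segments is common
  to both channels; the rest are channel-specific, drawn from separate RNG
  substreams so that changing ρ only adds or removes filaments without
  reshuffling the ones already present.
* **Radial offset**: channel B can be displaced toward the nucleus
  exterior by `radial_offset_nm` (literature value for the lamin B1 vs
  lamin A/C offset: ~15–20 nm).  In the top view, where that offset is
  out of plane, it is applied as a lateral translation of the channel-B
  skeleton with the same magnitude — this reproduces its decorrelating
  effect on the measured colocalization.
* **Shared intensity modulation**: both channels are multiplied by the
  same smooth random field (amplitude 0.4, correlation length 1 µm).
  Real lamina images show µm-scale brightness variation (local lamin
  density, labeling efficiency) that is common to both channels because
  both stain the same shell.  This shared coarse-scale variance is what
  keeps the *confocal* correlation high: a wide PSF averages away the
  channel-specific fine structure but leaves the shared modulation as the
  dominant variance.  Without it, Pearson's r would be almost
  blur-invariant (shared and unique variance shrink alike under
  convolution) and the well-known confocal inflation of colocalization
  would not be reproduced.  The 5 µm top-view field holds ~25 modulation
  patches, enough for the shared variance to be reliably present in every
  scene.

`render_image()` applies the forward optics model: isotropic Gaussian PSF
of the configured lateral FWHM (241 nm confocal / 60 nm STED — the
smallest measured line widths of the two modalities), box integration to
30 nm detector pixels, joint scaling so the brightest noiseless pixel has
expectation `photons_peak` (default 500, photon-counting detector),
axially Gaussian-weighted 3-slice z-stacks (step 100 nm), Poisson shot
noise, Gaussian read noise (SD 1 count) and rounding to nonnegative
integer counts.  A Gaussian is used as the effective PSF of both
modalities: it is the standard surrogate and it makes the expected
broadening closed-form testable (σ_obs² = σ_true² + σ_PSF²).  Defaults
that are *not* established numbers (photon budget, read noise, mesh
statistics, modulation) were chosen once as realistic values for a
photon-counting STED/confocal acquisition and are documented here.

```{r}
library(laminq)
scene  <- scene_config("mid_plane")
truth  <- build_lamina_scene(scene, seed = 1)
stack  <- render_image(truth, optics_config("sted", seed = 1))
stack
```

## Thickness measurement

`measure_thickness()` composes three steps:

1. `segment_rim()` — the nucleus is masked by thresholding a smoothed
   copy at 0.35× the Otsu level (below Otsu on purpose: the rim is not
   uniformly bright, and the mask must keep the interior plus dim rim
   arcs in one component), the largest filled component is taken, and its
   boundary is expressed as a radius function r(θ) about the centroid.
   Each direction is refined to the radial intensity ridge (the lamina
   centre line) and a weighted 8-harmonic Fourier series is fitted to
   r(θ), with weights equal to the local ridge prominence, so directions
   where the rim is dim are interpolated from their bright neighbours.
   Points and outward normals come analytically from the fitted curve.
   This assumes a star-convex nucleus — true of normal interphase nuclei,
   *not* of strongly dysmorphic ones (herniations, donut shapes), which
   are outside this package's scope.
2. `sample_profiles()` — five anchors (the standard per-cell protocol) at
   equally spaced arc-length fractions; the image is sampled along the
   outward normal over ± 3.5× the expected FWHM at `pixel_size/3`
   spacing.  Sampling uses interpolating Catmull–Rom cubic interpolation
   rather than bilinear: the tent kernel of bilinear interpolation adds
   ~p²/6 of variance to a peak only two pixels wide, a measurable bias at
   60 nm FWHM on 30 nm pixels, while the Catmull–Rom kernel adds
   essentially none.
3. `fit_gaussian_profile()` — Levenberg–Marquardt least squares of a
   Gaussian over a two-level step baseline (nucleoplasm level inside,
   background outside, the step smoothed by the same σ).  The two-level
   baseline reflects the diffuse lamin signal present in the nucleoplasm;
   a single-constant baseline is available as a flag.  A fit is *rejected*
   (never an exception) when R² < 0.8 or σ hits its bounds
   [spacing/2, half-window/3].  The upper bound is the operational version
   of "no accurate FWHM determination possible": a fitted peak wider than
   ~0.8 of the half-window has no baseline support left in the window and
   is invariably a pseudo-peak riding on background structure.  Rejected
   positions are excluded from the per-cell mean ± SD, with
   `n_attempted`/`n_used` recorded.

**Pixelation correction.**  The detector pixel integrates over a 30 nm
box, which adds a²/12 = 75 nm² to the fitted variance — a 5–10% width
inflation for a 60 nm peak.  `measure_thickness()` therefore applies the
standard pixelated-Gaussian correction σ² → σ² − a²/12 by default
(`pixel_correction = FALSE` restores the raw fitted widths).  The
`profile_fit` object itself always satisfies FWHM = 2√(2 ln 2)·σ exactly
for its own fitted σ.

With these choices, a simulated 14 nm lamina imaged with 60 nm STED
optics measures ≈ 63 nm — within a few percent of the dense numerical
top-hat ⊗ Gaussian oracle (≈ 60.8 nm) and of the PSF width itself, which
is precisely the sub-resolution behaviour the method is known for: below
the diffraction (or depletion) limit the FWHM measures the instrument,
not the shell.

## Deconvolution

`richardson_lucy()` implements the classic multiplicative
maximum-likelihood restoration for Poisson data under a Gaussian PSF,
with reflect padding (flux conserved to < 1%).  The two protocol knobs
are an iteration cap (default 40) and an SNR estimated from the image
histogram as 3·√(max/min⁺).  The smallest *strictly positive* value is
used as the divisor because background-subtracted images routinely
contain exact zeros.  The SNR sets the stopping tolerance as
stop_tol = 1/SNR² (mean relative change per iteration); this mapping is a
package convention — documented and configurable — chosen so that noisier
images stop earlier instead of amplifying noise.  Deconvolution is an
optional pipeline stage; every acceptance property of the measurements
holds with and without it.

## Colocalization

`costes_thresholds()` fits the orthogonal (total least squares)
regression ch2 = a·ch1 + b and lowers T1 from the channel-1 maximum along
the sorted unique intensities, with T2 = a·T1 + b, until the pixels below
*both* thresholds (the original formulation; "either" is a flag) show
Pearson r ≤ 0 or fewer than 2 pixels remain.  The scan is evaluated with
an algebraically identical vectorized formulation — pixel i leaves the
below-set when T1 drops under max(ch1ᵢ, (ch2ᵢ−b)/a), so sorting by that
exit threshold yields every candidate's statistics from cumulative sums —
which turns an O(n²) scan into O(n log n).  The brute-force scan is kept
in the test suite as the independent oracle.

`coloc_report()` returns `pearson_global` (all pixels), `pearson_coloc`
(pixels above threshold in either channel; the default comparison
statistic) and `pearson_below` (the excluded set, ≤ 0 at termination by
construction).  When the regression slope is not positive, Costes
thresholds do not exist; the report then falls back to the global
coefficient and flags itself `degenerate` — the natural reading of "no
positive correlation anywhere", and the behaviour needed for uncorrelated
scenes (ρ ≈ 0), where the principal axis of the intensity cloud is
unstable.  Top-of-nucleus planes are analysed whole; mid-plane images are
not used for colocalization.

`dual_profile()` samples both channels along a straight ROI at
pixel_size/3 spacing (bilinear, as is conventional for display profiles —
normalized traces are insensitive to the interpolation kernel) and
normalizes each trace to its own maximum.

## Statistics

`welch_t_test()` is the two-sided unequal-variance Student's t-test
(Welch statistic, Satterthwaite degrees of freedom) — in practice what
"Student's t-test, unequal variances" means — via `stats::t.test()`.
`p_stars()` maps p-values with the inclusive thresholds
\* ≤ 0.05, \*\* ≤ 0.01, \*\*\* ≤ 0.001, \*\*\*\* ≤ 0.0001.
`build_table()` aggregates measurement rows into per-group mean ± SD
with n, all pairwise Welch tests, and a smallest-measured-value summary
(the effective-resolution statistic).  By default values are averaged per
cell first, so cells are the unit of replication (positions within a cell
are strongly dependent); per-position testing is available behind a flag.
Raw p-values are reported without multiplicity adjustment, matching
common practice for these small tables.  Sample SD (n−1) is used
throughout.

## Numerical and interface conventions

* Pixel centres sit at integer coordinates, 1-based, `(row, col)` =
  `(y, x)`; all physical distances are nm.  Signed profile distance is 0
  at the rim crossing and negative on the nucleoplasm side.
* Convolution is FFT-based with reflect padding and a 4σ kernel radius;
  supersampled scenes are box-binned to detector pixels (the supersample
  pitch must divide the pixel size).
* Simulated noisy stacks are integer photon counts and round-trip
  bit-exactly through 16-bit TIFF; noiseless expectations are written as
  32-bit float, rescaled to [0, 1] with the scale recorded in the JSON
  sidecar.  There is no OME-XML writer in this package's dependency set;
  pixel size, z step and channel names travel in the sidecar, and
  `read_stack()` accepts an explicit pixel-size override which always
  wins over metadata (a thickness in nm is meaningless without a pixel
  size, so a plain TIFF without either is an error).
* All randomness flows from explicit seeds: scenes use one seed with
  fixed substream offsets for shared/unique filaments and the shared
  modulation; rendering noise uses the optics seed; `run_pipeline()`
  derives every per-image seed from the single config seed.

## Problem sizes in the test suite

Unit tests run on reduced scenes (nucleus semi-axes 1.2 × 0.9 µm, 2 µm
top fields); the acceptance suite uses the default study conditions with
10 simulated cells or 10 seeds per property and a 5 × 10 ρ-grid for
colocalization recovery.  These sizes were chosen so the whole suite runs
in minutes on a single core while keeping every Monte-Carlo margin well
away from its threshold.

## What passing tests do and do not show

The simulator emulates the *geometry and statistics* the measurement
protocol assumes: a thin shell or meshwork, a Gaussian effective PSF,
detector binning, shot and read noise, shared labeling-density structure
and a controllable inter-channel overlap with known ground truth.  It
does not emulate antibody-complex size (which broadens real stained
lamina profiles well beyond the bare PSF), depth-dependent aberrations,
STED depletion-donut physics, photobleaching, drift, nucleoplasmic
reticulum invaginations, or dysmorphic nuclear shapes.  Passing the
recovery suite therefore shows the *pipeline* is correct and unbiased
under its stated model, not that any particular biological number is
reproduced; conversely, the systematic confocal > STED ordering of both
thickness and colocalization — the study's central qualitative finding —
emerges from the model without tuning.

## Known limitations

* Star-convex rim model: strongly lobed or herniated nuclei will not
  segment correctly; supply a manual ROI (`rim` argument) in that case.
* The Costes scan on near-uncorrelated channels terminates at an
  essentially arbitrary threshold (the below-set correlation is a ~0
  fluctuation); the report is still well-defined but `pearson_coloc`
  inherits that variability.  This is a property of the method, not of
  the implementation.
* The SNR → stopping-tolerance mapping in deconvolution is a convention;
  commercial implementations use undisclosed regularization.
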