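# laminq

Quantification of nuclear lamina layer thickness and lamin A/C–lamin B1
colocalization from confocal (CSLM) and STED fluorescence images, with a
ground-truthed two-channel simulator that makes every stage of the
pipeline verifiable.

## The problem

The nuclear lamina — the lamin filament meshwork lining the inner nuclear
membrane — is ~14 nm thick, far below light-microscope resolution.  Two
standard quantities are still extracted from lamin-stained nuclei:

* **Apparent layer thickness.**  At the nuclear mid-plane the lamina is a
  bright rim.  An intensity profile I(x) perpendicular to the rim is
  fitted with a Gaussian over a smoothed two-level step baseline,

      I(x) = A·exp(−(x−c)²/2σ²) + b_in + (b_out−b_in)·Φ((x−c)/σ),

  and the thickness is reported as FWHM = 2√(2 ln 2)·σ ≈ 2.3548 σ,
  averaged over five positions per cell.  For a sub-resolution shell this
  FWHM measures the effective optical resolution (~241 nm confocal,
  ~60 nm STED), which is exactly what makes it useful as a
  modality-comparison statistic.
* **Colocalization.**  At the top of the nucleus the two lamin networks
  appear as meshworks.  Pearson's correlation coefficient of the two
  channels is computed after Costes automatic thresholding: lower the
  thresholds (T1, T2 = a·T1 + b from the orthogonal regression of ch2 on
  ch1) until the pixels below both show no positive correlation, then
  correlate the pixels above threshold.

The package also provides Richardson–Lucy deconvolution configured by an
iteration cap and a histogram-based SNR (3·√(max/min⁺)), Welch
two-sided unequal-variance t-tests with the usual star convention
(\* ≤ 0.05 … \*\*\*\* ≤ 0.0001), and a synthetic scene generator
(elliptical mid-plane shell or top-view filament meshwork, Gaussian PSF,
detector binning, Poisson + read noise) with known thickness, channel
overlap ρ and radial offset, so recovery can be tested against ground
truth.  See the vignette `vignettes/lamina-quantification.Rmd` for the
model details and design decisions.

## Worked example

```r
library(laminq)

# a 14 nm lamina, rendered through STED and confocal optics
scene <- scene_config("mid_plane", true_thickness_nm = 14)
truth <- build_lamina_scene(scene, seed = 1)
sted  <- render_image(truth, optics_config("sted", seed = 1))
measure_thickness(sted, channel = "laminA", expected_fwhm_nm = 60,
                  modality = "sted")
#> lamin layer thickness, cell cell1, channel laminA (sted)
#>   FWHM = 62.2 +/- 3.1 nm  (n = 5 of 5 positions)

conf <- render_image(truth, optics_config("confocal", seed = 1))
measure_thickness(conf, channel = "laminA", expected_fwhm_nm = 241,
                  modality = "confocal")
#> lamin layer thickness, cell cell1, channel laminA (confocal)
#>   FWHM = 232.5 +/- 11.9 nm  (n = 5 of 5 positions)
```

The same 14 nm shell reads ~62 nm under STED and ~233 nm under confocal
optics: both measurements sit at their modality's resolution limit, not
at the true shell width.

```r
# colocalization of a half-shared meshwork under STED optics
top <- build_lamina_scene(scene_config("top", shared_fraction = 0.5),
                          seed = 2)
coloc_report(render_image(top, optics_config("sted", seed = 2)))
#> Costes-thresholded colocalization
#>   regression   : ch2 = 0.9969 * ch1 + -1.154 (orthogonal)
#>   thresholds   : T1 = 4, T2 = 2.834
#>   Pearson r    : global 0.5747 | coloc 0.5718 | below -0.0098
#>   pixels used  : 27970 of 28224

# group comparison of published per-nucleus Pearson values
ref <- lamin_pearson_reference()
rec <- data.frame(group = rep(c("CSLM", "STED"), each = 6),
                  cell_id = rep(1:6, 2),
                  pearson = c(ref$cslm, ref$sted))
build_table(rec, value = "pearson", group = "group")
#> Group summaries (pearson, mean +/- SD, smallest = minimum measured value):
#>   CSLM                         0.907 +/- 0.0278 (n = 6), smallest 0.873
#>   STED                         0.755 +/- 0.0377 (n = 6), smallest 0.707
#> Pairwise Welch t-tests (two-sided, unequal variances):
#>   CSLM vs STED: t = 7.98, df = 9.2, p = 1.99e-05 ****
```

The below-threshold correlation is ≤ 0 (the Costes termination
contract), and the coarser confocal PSF yields systematically higher
colocalization than STED — the resolution-inflation effect the
comparison is designed to expose.

A thin command-line wrapper over the same functions is installed at
`inst/cli/laminq` (subcommands `simulate`, `deconvolve`, `thickness`,
`coloc`, `profile`, `report`, `run`).

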