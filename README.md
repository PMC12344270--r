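# rhizochron

Root growth phenology and seasonal root-length budgets from minirhizotron
image time-series.

## The problem

In alpine grassland most plant biomass is belowground, yet root growth
dynamics are rarely measured: roots are observed through transparent
minirhizotron tubes installed at ~45° in the soil, scanned weekly at high
resolution, and the resulting thousands of images must be turned into
standing root length per soil depth — then into phenology (when does root
growth start and stop?) and seasonal budgets (how much is gained per
treatment period, how much is lost over winter?) under factorial snowmelt
× drought manipulations.

rhizochron implements that whole chain as tested, seed-reproducible R
code, for people analysing rhizotron campaigns or method developers who
need a pipeline with known ground truth:

* **Image preparation** — tape masking, scan-pair merging, registration
  to the tube's first image by phase correlation, de-striping,
  percentile contrast normalization.
* **Segmentation** — a deterministic multiscale Hessian ridge
  (tubeness) operator with hysteresis thresholding, plus a pixel
  precision/recall harness that scores *any* mask source, including
  neural models.
* **Traits** — Guo–Hall skeletonization (compiled) with length by
  polygonal resampling of the traced skeleton chains (within ~1% of
  analytic length at every orientation); per-pixel diameters from the
  distance transform (11 classes, 0–1 mm in 0.1 mm steps plus >1 mm);
  cylindrical surface area; depth splitting via
  `depth = s · sin(angle)`; everything per cm² of image area.
* **Phenology** — snowmelt detection from the topsoil winter plateau,
  growing degree hours `Σ max(T − 5 °C, 0)`, per-plot thin-plate spline
  smoothing (mgcv), and t20/t80: the first times the smooth surpasses
  20%/80% of the seasonal amplitude (max minus first value), in days
  and degree hours.
* **Seasonal accounting** — net changes per treatment period
  (pre-treatment, drought weeks 0–5 and 5–10, autumn, winter) that
  telescope exactly, winter losses relative to standing length and to
  the previous season's gain, and block-aware permutation contrasts.
* **Synthetic data** — a generator that emulates the 3×3 snowmelt ×
  drought factorial (45 plots, 90 tubes) with programmable effects and
  full ground truth: logistic growth curves, analytic strand polylines
  rendered into degradable scan pairs, exact winter losses.

## Worked example

Render one synthetic tube, measure it through the classical pipeline,
and extract its phenology:

```r
library(rhizochron)

curve <- gen_growth_curve(drought = "5wk", seed = 3)$curve
curve
#> <growth_curve> 5wk: max 46.74 mm cm^-2, t20 DOY 173.8, t80 DOY 191.9

geom <- synth_tube_geometry()
tube <- gen_image_sequence(geom, curve, seed = 5)
traits <- measure_tube_series(tube, segmentation = "classical")
subset(traits, layer == "total" & doy == 206,
       select = c(doy, length_mm, length_per_area))
#> # A tibble: 1 × 3
#>     doy length_mm length_per_area
#>   <dbl>     <dbl>           <dbl>
#> 1   206      97.5            44.5
```

The measured 97.5 mm of root in this 2.2 cm² window (44.5 mm cm⁻²)
tracks the generator's analytic truth for that date (99.3 mm) to
within 2%. Thresholds for a whole synthetic cohort:

```r
co <- gen_cohort(experiment_design(seasons = 2020), seed = 11)
ph <- cohort_phenology(co)
summary(ph$t80_doy - ph$true_t80)   # per-plot t80 recovery error, days
```

An end-to-end run — generate, smooth, account, contrast — with all
outputs written as CSV plus a manifest:

```r
res <- run_pipeline(pipeline_config(out_dir = "run1", seed = 20200601))
res$contrast
#> <permutation_contrast> drought vs control: effect 5.646, p = 0.001 (999 perms, n = 90)
```

The effect is the weeks-0–5 net root-length gain of droughted plots
over controls (mm cm⁻², block-aware permutation p-value) — the
generator programs a ×1.19 early-drought stimulation, and the pipeline
recovers it.

A thin command-line front end is installed at
`system.file("cli", "rhizochron", package = "rhizochron")` with
`run`, `generate`, `eval-seg` and `traits` subcommands.

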