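---
title: "From rhizotron scans to root phenology: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From rhizotron scans to root phenology: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizochron)
```

rhizochron turns repeated minirhizotron scans of an alpine grassland into
community root-growth phenology and seasonal root-length budgets under a
factorial snowmelt x drought experiment. This vignette explains the models
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical choices a user should know about before trusting a number.

## The measurement chain

A minirhizotron is a transparent tube installed at an angle (target 45°,
realized 32–61°) in the soil; a cylindrical scanner inside produces an
unrolled 360° image of the tube–soil interface, two scans per tube and
date to cover the belowground extent. The pipeline prepares each scan pair
in five steps:

1. **Tape masking.** The light-blocking tape near the soil surface is
   replaced by black pixels using a per-tube mask (`apply_tape_mask()`).
2. **Merging.** The pair is stacked into one raster; in the overlap band
   the upper scan wins (`merge_scan_pair()`). The overlap is a config
   parameter (default 0 for external data; the generator uses 20 px).
3. **Registration.** Each merged image is aligned to the tube's first
   image by the integer planar shift that maximizes the phase-correlation
   peak (`register_to_reference()`). Only rigid translations are modelled
   — the tubes themselves cannot deform; residual drift comes from
   scanner placement. Out-of-canvas pixels are zero-filled.
4. **De-striping.** Column medians are detrended with a wide running
   median and the per-column residual offset subtracted
   (`remove_stripes()`). This removes the additive column banding typical
   of tube scanners while passing stripe-free images essentially
   unchanged (≤ 2 grey levels).
5. **Normalization.** A linear rescale maps the 1st/99th intensity
   percentiles to 0/255 (`normalize_contrast()`), putting scans taken
   under different illumination on one scale.

## Segmentation

Roots appear as bright, curvilinear, roughly constant-width ridges on a
darker textured background. `segment_roots()` computes a multiscale
Hessian ridge response (the scale-normalized magnitude of the negative
eigenvalue, the classical tubeness measure) over scales matched to root
widths of 0.1–0.6 mm, then keeps pixels by hysteresis: weak-response
pixels survive only in connected components that contain a
strong-response seed. Two guards matter in practice:

* an **intensity gate** — candidate pixels must also be brighter than
  `median + 3·MAD` of the frame. The ridge response alone leaves a dim
  halo around each root and fires on step edges; since roots are a
  minority of bright outlier pixels, the robust gate removes both.
* **hole filling and small-object removal** — enclosed background holes
  up to 25 px are filled (speckle holes fragment the skeleton into loops
  that inflate length), and components under 30 px are dropped. In the
  pipeline the tape band plus a 3-px margin is excluded: the black
  tape/soil step otherwise reads as a spurious horizontal ridge.

The hysteresis thresholds (15/5 response units on the normalized frame)
were tuned once on a held-out set of synthetic scenes and frozen. The
segmenter is a deterministic classical stand-in for a trained pixel
classifier: any externally produced mask — including one from a neural
model — can be scored through `evaluate_segmentation()` (pixel precision,
recall, F1) and fed to the trait extraction unchanged. On the default
synthetic benchmark the classical operator reaches mean pixel precision
and recall near 0.99; on real scans a trained model should be used and
this operator treated as a baseline.

## Root traits from binary masks

`split_by_depth()` is the workhorse. It thins the mask to a one-pixel
skeleton (Guo–Hall two-subiteration thinning, compiled; chosen over
Zhang–Suen because it leaves far fewer staircase artifacts), then
measures length by tracing the skeleton's chain paths (8-connected, with
diagonal steps that merely short-cut a corner pixel excluded) and
resampling each path polygonally: the sum of Euclidean chords between
chain points four steps apart, plus a closing chord for the remainder.
The choice matters: pure step-count estimators are orientation-biased —
the plain \(N_o + \sqrt2\,N_d\) chain sum overestimates circles by
~15%, and even the corner-count formula
\(\sqrt{N_d^2 + (N_d + N_o/2)^2} + N_o/2\) reaches +2.7% on oblique
lines near \(\tan\theta = 0.4\) — whereas polygonal resampling stays
within about 1% of analytic length at every orientation tested (lines,
diagonals, arcs, circles of width ≥ 2 px). An optional tip correction
(`max(EDT − 1, 0)` at skeleton endpoints) compensates the tip erosion of
thinning on flat-ended strokes; it is off by default because real and
rendered roots end in rounded caps that already compensate.

Per-pixel diameters are twice the Euclidean distance transform at
skeleton pixels minus one pixel (centre-to-centre correction: a 1-px line
then reads one pixel, 0.021 mm at 1200 DPI). Length is distributed to
skeleton pixels (half of each incident edge, rescaled to the traced
path total), so diameter-class sums and depth-layer sums
conserve the total length *exactly* by construction. Diameter classes are
half-open (0–1 mm in 0.1 mm steps, plus >1 mm; exactly 1.0 mm falls in
the >1 class — the boundary had to be fixed somewhere and the open left
edge keeps every class the same width). Branch-point pixels are flagged
and excluded from diameter summaries (junctions inflate the distance
transform) but not from binning, so conservation holds. Surface area uses
the cylindrical model \(\sum \pi d_i \ell_i\).

Image rows map to soil depth through the tube geometry:
`depth = (row − tape_rows)·(2.54/dpi)·sin(angle)`, anchoring the
along-tube distance at the soil surface (the tape edge). Whether the
field protocol anchors at the tape edge or the tube top is an
interpretation; the tape edge is used because the tape marks the soil
surface by construction. Layers are half-open ([0, 10), [10, bottom) cm
by default) and the deepest layer runs to the image bottom. All densities
are expressed per cm² of unmasked image area, which makes tubes with
different tape widths and installation depths comparable.

## Phenology

**Snowmelt** is read off the topsoil temperature: under a closed alpine
snowpack the soil sits on a ~0.3 °C plateau; melt-out is the first day
whose trailing 3-day mean of daily means exceeds 2 °C, provided no
≥ 5-day excursion below 1 °C follows within 60 days (a brief warm spike
before the true melt is thereby ignored, while the ordinary autumn
cool-down far later is not held against a candidate). The exact rule is
this package's own; published protocols rarely state one.

**Thermal time** is `compute_gdh()`: the hourly sum of `max(T − 5, 0)`.
"Degree hours above 5 °C" can also be read as a count of warm hours;
`count_hours = TRUE` switches to that reading, but the excess-sum is the
default because heat-sum phenology conventionally weights by the excess.

**Smoothing.** Each plot-season series is fitted with a thin-plate
regression spline (mgcv, GCV-selected smoothness). Replicate
observations on one day are aggregated to weighted means with weights
normalized to mean one — this makes the fit exactly invariant under
duplication of the dataset, which raw GCV is not. Two calibrations
matter for threshold extraction from saturating curves, both validated
on synthetic logistic curves with known crossings:

* `gamma = 0.7` (slightly less smoothing than plain GCV). Saturating
  curves have a sharp shoulder; oversmoothing rounds it and delays the
  apparent 80% crossing by 2–3 days at weekly sampling. Undersmoothing a
  little removes that bias at a small variance cost.
* For root series the baseline is 0 *by construction* (each season is
  expressed relative to its first scan) and the cumulative curve is
  monotone, so the seasonal amplitude is anchored at the season end
  (`amplitude_at = "end"`) rather than at the grid-wide maximum, which
  plateau wiggle otherwise inflates. Leaf series keep the grid maximum
  and get the 0.5 cm × 10-point snowmelt baseline pad
  (`pad_leaf_baseline()`).

**Thresholds.** t20/t80 are the first grid times (0.25-day grid; a daily
grid changes results by < 0.5 day) at which the smooth surpasses
first value + 0.2/0.8 of the amplitude (max value minus first value).
"First crossing" is deliberate: it is the natural reading of
"surpassing" and is robust to late-season dips. Each crossing is also
expressed in degree hours accumulated from snowmelt, and a max-scaled
rate per degree hour up to t80 (`0.8·amplitude / t80_gdh`) is reported —
one defensible reading of a "growth rate per GDH until 80% growth"
summary; alternatives (e.g. fitting a slope) exist and the quantity
should be compared across treatments, not across definitions. Under a
pure time shift with an identical post-melt temperature profile the
rate is invariant — the mechanism by which shifted snowmelt moves
growth phases without changing temperature-normalized growth rates.

## Seasonal accounting and contrasts

Seasons are partitioned at snowmelt, shelter placement, 35 and 70 days
after placement (exact-day equivalents of the 5/10-week treatments), and
the last scan. Period changes are net differences between the last scan
of a period and the last scan of the previous period, so deltas
telescope to the whole-season change exactly; periods without a scan are
flagged, never imputed. Winter change is first scan of the new season
minus last scan of the old, reported relative to both the previous
standing length ("declined by X%") and the previous season's gain ("X%
of the season's increase") — the two denominators answer different
questions and published figures use both.

Treatment contrasts use a block-aware permutation test: the effect is
the difference of treatment means and the null is built by permuting
labels within blocks, respecting the experiment's spatial blocking
without fitting a mixed model. The p-value uses the add-one estimator;
blocks with a single plot are excluded with a warning.

## The synthetic generator

The generator emulates the field campaign: a 3×3 factorial (snow
control/removal/addition × drought control/5-wk/10-wk), five blocks,
n = 5 plots per combination, two tubes per plot (90 tubes), weekly scans.
Its defaults *are* the study conditions: snow manipulation shifts
snowmelt by −4.7/+10.8 days; drought multiplies the growth rate by 1.19
in weeks 0–5 (both arms), 0.78 in weeks 5–10 (10-wk arm) and 1.38 for
28 days after shelter removal; winter removes 11% of standing length
after control/5-wk seasons and 17% after 10-wk drought. The community
cumulative curve is logistic (asymptote 40 mm cm⁻², rate 0.15 d⁻¹,
midpoint 25 d after melt — matching a peak-year seasonal increment of
~40 mm cm⁻² reached over ~8 weeks), with multipliers acting on the rate
inside their windows and ground-truth t20/t80 solved from the noiseless
curve. Measurement noise of weekly root lengths is not characterized in
the field, so it is an explicit knob (`noise_sd_fraction`, default 0.05
of the seasonal maximum); between-plot and between-block lognormal
variation of the asymptote default to 10% and 5%, typical of plot-scale
heterogeneity in species-rich grassland.

Rhizotron scenes are rendered as biased random-walk strands (downward
drift, curvature-limited, reflected at the walls) on a textured soil
background. Strands avoid already-occupied soil — roots tile the tube
surface rather than run on top of each other — which keeps the analytic
polyline length and the skeleton-measured length of the union mask
within 5% of each other; occasional steep crossings remain. Growth is
"frontier" growth: strands extend from their tips so that the drawn
length exactly equals the growth curve's standing length times the image
area at every date, and per-layer truth comes from the polylines, not
the raster. Strand widths draw 85% from 0.12–0.30 mm and 15% from
0.30–0.60 mm, reproducing the observed dominance of very fine roots
(≥ 80% of length below 0.3 mm). Winter loss removes whole strands
(roots disappear rather than erode), with one strand tip-trimmed so the
programmed loss fraction is hit exactly. Degradations — additive column
stripes, per-date planar drift up to ±5 px, brightness drift ±12 — are
applied after the truth mask is taken, so truth lives in reference
coordinates and registration is genuinely exercised.

What the generator does **not** emulate: photorealistic soil (its
background is Gaussian-textured), root branching topology, diameter
growth over time, partial root decay, herbivory, soil-moisture physics,
or the appearance variability of real field scans (condensation,
scratches, fauna). Passing tests therefore demonstrate that the
*pipeline machinery* is correct and unbiased under known ground truth —
not that the classical segmenter would reach any particular accuracy on
real imagery; on real data the segmentation stage should be replaced by
a trained model and scored with the same harness.

## Problem sizes and determinism

Every randomized artifact takes an explicit seed, fans it out through a
deterministic sub-stream derivation, and reproduces bit-identically;
`run_pipeline()` writes a manifest (seeds, parameters, versions) from
which any output table can be regenerated. The bundled analyses are
desk-scale by design: synthetic tubes default to a 420×300 px window at
600 DPI (a 0.1 mm root is then 2.4 px wide), the replicate end-to-end
experiment uses 20 cohorts of 30 tubes × 10 scan dates at 220×170 px
with scans at the period-defining dates only, and the phenology
recovery study uses 100 plots at weekly sampling. Densities (mm cm⁻²)
are window-size-free, so the small windows change variance, not
meaning.

## Known limitations

* Skeleton-based length under-counts overlapping roots; at standing
  densities above ~80 mm cm⁻² (two accumulated seasons) the bias reaches
  ~10% and treatment effects measured on such scenes are compressed.
  The replicate experiment therefore contrasts the first season, where
  measurement is at its most linear — as a field analysis would prefer
  its first undisturbed season.
* The classical segmenter's false positives cluster on bright soil
  features; they are stable per tube and largely cancel in net changes
  but add noise to period deltas.
* Integer-pixel registration suffices for rigid tubes; sub-pixel drift
  below 1 px is not corrected.
* `detect_snowmelt()` assumes an insulating snowpack (winter plateau
  near 0 °C); it is not applicable to sites with bare-ground winters.
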