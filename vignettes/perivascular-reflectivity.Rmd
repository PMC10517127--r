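---
title: "Corrected perivascular reflectivity on en-face OCT/OCTA: methods and design notes"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(perivasc)
```

## The measurement problem

Eyes with branch retinal vein occlusion (BRVO) differ in how often macular
edema recurs, and recurrence drives the intravitreal injection burden. A
candidate imaging correlate is the brightness of the tissue immediately
around the deep capillary plexus (DCP) vasculature on en-face structural
OCT: congested vessels with altered perivascular tissue should read as
locally hyper-reflective. Raw en-face reflectivity, however, depends on
signal strength, media opacity and device gain, so an absolute mean is not
comparable across eyes. The package implements a *corrected* perivascular
reflectivity that is a within-image ratio and therefore invariant to
uniform gain:

1. Split the co-registered 3.0 x 3.0 mm structural/OCTA en-face pair
   (nominally 320 x 320 px) into four equal quadrants; select the quadrant
   containing the occlusion ("obstructive") and, for reference, the
   diagonally opposite ("contralateral") quadrant.
2. Binarize the OCTA quadrant at its mean pixel value + 2 standard
   deviations. Pixels above this threshold carry definite, abundant flow.
3. Keep only connected particles of at least 3 pixels (about 28 um at this
   geometry, the calibre of the smallest resolvable vessels); the surviving
   pixels are the high-signal-strength (HSS) area.
4. Transfer the HSS mask to the structural image and form

   corrected reflectivity = mean structural intensity on the HSS area /
   mean structural intensity of the full en-face image.

The ratio is exactly 1 when the structural image is constant, is unchanged
when the structural image is multiplied by any positive gain, and increases
strictly when intensity is added only on the HSS area. These three
identities are enforced by tests, and they are the reason the metric is
comparable across scans.

Secondary quantifications follow the same conventions: vessel density is
the percentage of OCTA pixels above the plain mean ("Mean" auto-threshold)
after excluding the foveal avascular zone (FAZ), and FAZ morphometrics
(area, perimeter, circularity) are computed from a supplied binary mask.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_particle_px` | 3 | minimum HSS particle area, inclusive (>= 3 px) |
| `connectivity` | 8 | neighbourhood for particle connectivity |
| `sd_type` | `"sample"` | SD convention in mean + 2 SD (n - 1 denominator) |
| `strict` | `TRUE` | binarize with `>` rather than `>=` |
| `threshold_scope` | `"quadrant"` | region whose mean/SD define the threshold |
| `denominator_scope` | `"image"` | region whose structural mean normalizes |
| `min_quality` | 65 | device image-quality gate, inclusive |

Where the source procedure is ambiguous both readings are provided and the
default is the one we judged operative:

* **"bigger than three consecutive pixels" vs "three pixels or more".** The
  size filter is inclusive (area >= 3) by default because the explicit
  rationale given for the floor — the ~20 um lateral resolution and the
  >= 15 um calibre of the smallest arterioles and venules — is an argument
  for *including* 3-pixel particles. `min_particle_px` is configurable.
* **Threshold scope.** The threshold statistics come from the analyzed
  quadrant by default (the quadrant is what gets binarized); whole-frame
  statistics are available via `threshold_scope = "image"`. The denominator
  is the full-image structural mean (one overall value per eye), with a
  quadrant-only option.
* **Strict comparison.** `>` rather than `>=`, so a constant region yields
  an empty mask instead of an all-true one.
* **SD convention.** Sample SD (n - 1), matching the statistics common
  imaging software reports; population SD is selectable.
* **Connectivity.** 8-connectivity, the convention of the usual
  particle-analysis tools; 4-connectivity is selectable.
* **Contralateral quadrant.** Defined here as the diagonally opposite
  quadrant — the corner geometrically farthest from the occlusion — since
  no definition is otherwise fixed; it can be overridden per eye.

Degenerate inputs never propagate silently: an empty HSS mask raises a
typed `"no HSS area"` error, a zero-mean structural image a degenerate-image
error, and both conditions are distinguishable by condition class.

A note on feasibility: for a two-level intensity histogram with bright
fraction f, mean + 2 SD exceeds the bright level whenever f > 0.2, so a
quadrant more than ~20% covered by uniformly bright vessels has *no* pixels
above threshold. Real angiograms escape this because flow signal is
heterogeneous; the synthetic generator reproduces that heterogeneity (see
below), and the analysis reports the empty-mask error rather than a silent
zero when an image genuinely has no HSS area.

## Perimeter and circularity

The FAZ perimeter uses a Crofton (intercept-count) estimator: 2 x 2 pixel
configurations of the padded mask are counted and weighted by the expected
number of intersections with random lines in four directions. Unlike a
crack-length (edge-count) perimeter, which overestimates a digitized disc
by 4/pi and would cap its circularity near 0.62, the Crofton estimator is
close to unbiased for smooth outlines: a digitized disc of radius 40 px
comes out within ~1% of 2*pi*r and its circularity 4*pi*A/P^2 lands at
~0.99. Because the device software whose FAZ readings this mirrors does not
document its estimator, absolute circularity values are comparable within
one estimator, not across estimators; this is flagged in the function
documentation.

## The statistics chain

* **Agreement:** ICC from the two-way ANOVA mean-square decomposition;
  default two-way random effects with absolute agreement, i.e. ICC(2,1)
  for single measures and ICC(2,k) for average measures, the standard
  choice for two interchangeable graders. The consistency forms
  (ICC(3,.)) are selectable, since the exact variant used on the original
  gradings is unreported.
* **Group comparison:** one-way ANOVA followed by all three pairwise
  independent t-tests with Bonferroni correction (adjusted P = raw P x 3,
  capped at 1). Post-hoc tests are equal-variance Student by default —
  the default of the statistical package the original analysis names —
  with Welch selectable.
* **Paired quadrants:** classical paired t-test of obstructive vs
  contralateral corrected reflectivity; all-zero differences return the
  defined degenerate result t = 0, P = 1.
* **Regression:** per predictor, a simple linear fit of the z-scored
  outcome on the z-scored predictor, so the univariate standardized beta
  equals the Pearson correlation exactly. Binary categorical predictors
  are coded 0/1 before standardization. Predictors with univariate
  P < 0.2 enter the multivariate model. Missing values are dropped
  listwise per model and the per-model n is reported. A rank-deficient
  multivariate design raises an error naming the collinear predictors.
* **Duration sub-analysis:** eyes are split at 36 months of disease,
  compared by independent t-tests, and a standardized regression of
  reflectivity on injections/year is fitted within each stratum.

## What the synthetic cohort emulates

No scans are distributed with the original study, so validation runs on a
seeded generator whose defaults are the study conditions: three arms of
45/30/45 eyes (recurrent BRVO, indolent BRVO, control), 320 x 320 px over
3.0 x 3.0 mm.

**Images.** A vessel tree is grown as a correlated random walk with
branches; branch origins are steered towards the quadrant currently
poorest in vessels, because a healthy capillary plexus is spatially even
and because a vessel-saturated quadrant would push its mean + 2 SD
threshold over the 8-bit ceiling (see the feasibility note above). Walks
entering a quadrant holding more than 1.4x its share of the coverage
target are terminated there, which bounds per-quadrant coverage while
keeping the tree connected. The OCTA image is Gaussian background
(mean 30, SD 10) plus Rayleigh-like speckle (scale 8), with heterogeneous
flow signal N(175, 40) on the vessel core and N(155, 40) on its 1-px
margin. The structural image is Gaussian background N(100, 12) with a
fixed +23.5 elevation on vessel-adjacent pixels in every eye. Both are
quantized to 8 bits.

**The planted effect.** Each BRVO eye receives a perivascular elevation
delta added to the structural image on the rim around vessels (dilation by
2 px minus the vessel), restricted to the obstructive quadrant. Delta is
Gamma-distributed per group — mean 53 (SD 18) for recurrent, 13 (SD 10)
for indolent, exactly 0 for controls — giving delta >= 0 by construction.
The group means were calibrated once so that the *measured* group means of
corrected reflectivity land near 1.31 / 1.22 / 1.19; the per-eye spreads
were chosen so that planted group ordering is recoverable at the study's
arm sizes, and are narrower than clinical cohorts (which carry biological
heterogeneity the generator does not model). About a quarter of HSS pixels
fall on the rim, which is the lever arm through which delta moves the
metric; the effect of delta on the measured ratio is ~0.0023 per intensity
unit and is size-invariant between 128 and 320 px rasters.

**Covariates.** Injections/year is linearly linked to delta
(slope 0.045, Gaussian noise, truncated at 0), refractive error receives a
weak positive link, and the remaining covariates (age, sex, IOP, BCVA,
durations, thicknesses) are drawn from group-typical normals. Setting
`inj_beta` derives the link noise so that the correlation between
injections/year and delta equals a chosen value; note that the correlation
against the *measured* reflectivity is attenuated below that plant, since
measurement noise in the outcome shrinks a correlation even though it
leaves a regression slope unbiased. `simulate_records()` is the tabular
arm of the generator (same covariates, reflectivity drawn from a linear
approximation of the pipeline: 1.19 + 0.0023 delta + N(0, 0.007)) for
power and type-I-error studies needing thousands of replicates.

**What passing tests do and do not show.** The generator demonstrates that
the pipeline recovers planted effects of the configured size and direction
under speckle, quantization and vessel-geometry variation. It does not
model projection artifacts, segmentation error, media opacity, motion, or
biological covariance between vessel architecture and disease severity —
so passing tests validate the computation, not clinical performance on
real scans.

## Problem sizes and numerics

Validation uses 100 replicate cohorts at 128 x 128 px for the
ordering/ANOVA recovery study (the planted effect is size-invariant, and a
quadrant at this size still holds hundreds of HSS pixels), a single
500-eye cohort for regression recovery, 1000 tabular replicates for
type-I-error rates, and single cohorts at the native 320 x 320 px for the
worked examples and the acceptance script. All randomness flows from
integer seeds through R's default generator; rendering and measurement are
deterministic given (seed, config), and byte-identical reruns are enforced
by test. Intensities are quantized to integers before analysis, matching
8-bit acquisition; connected components are labeled by a breadth-first
search in compiled code and cross-checked in tests against an independent
flood-fill and against an external labeling implementation.

## Known limitations

* The Crofton perimeter choice makes FAZ circularity values
  estimator-specific (see above).
* Only binary categorical predictors are supported in the regression
  suite, which covers every covariate in scope.
* The generator's group spreads are tighter than clinical SDs; it
  validates recovery of the planted structure, not the attainable power on
  real cohorts.
* No projection-artifact removal, no B-scan processing, no registration:
  structural/OCTA pairs are assumed co-registered as acquired.
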