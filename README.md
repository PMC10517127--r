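# perivasc

Quantification of **corrected perivascular reflectivity** on paired en-face
structural OCT / OCT angiography (OCTA) images of the retinal deep capillary
plexus, for researchers studying branch retinal vein occlusion (BRVO) and
macular edema recurrence.

Raw en-face reflectivity is confounded by signal strength and device gain.
The metric implemented here is a within-image ratio and therefore
gain-invariant. For one image quadrant *Q* (the quadrant containing the
occlusion, or a reference quadrant):

1. threshold the OCTA quadrant at **T = mean + 2 SD** of its pixel values;
2. keep connected particles of the binarized mask with area **>= 3 px**
   (~28 µm at 3.0 mm / 320 px) — the **high-signal-strength (HSS)** area;
3. transfer the HSS mask to the structural image and compute

   **R_corr = mean(structural | HSS) / mean(structural | whole image)**

R_corr = 1 for a constant image, is invariant to uniform structural gain,
and rises when the tissue around flow-bearing vessels is hyper-reflective.
The package also provides vessel density with foveal-avascular-zone (FAZ)
exclusion, FAZ morphometrics (area, Crofton perimeter, circularity
4πA/P²), the associated statistics chain (ICC(2,1)/ICC(2,k) agreement,
one-way ANOVA with Bonferroni post-hoc t-tests, paired obstructive-vs-
contralateral comparison, standardized-β regression with the P < 0.2 entry
rule, disease-duration sub-analysis), and a fully seeded synthetic cohort
generator so the whole pipeline is testable without patient data.

## Worked example

```r
library(perivasc)

cfg <- synthetic_config(seed = 7, side_px = 128,
                        n_per_group = c(recurrent = 6L, indolent = 4L,
                                        control = 6L))
cohort <- generate_cohort(cfg)
cohort
#> <synthetic_cohort> 16 eyes (control 6, indolent 4, recurrent 6), 128 x 128 px, seed 7

eye <- cohort$eyes[[1]]
corrected_reflectivity(eye$structural, eye$octa,
                       cohort$records$measure_quadrant[1])
#> <reflectivity_result> quadrant Q4
#>   corrected reflectivity : 1.2409
#>   mean on HSS            : 129.943
#>   overall en-face mean   : 104.713
#>   threshold (mean + 2SD) : 150.974
#>   HSS area / particles   : 369 px / 2

tab <- analyze_cohort(cohort)
round(tapply(tab$corrected_reflectivity, tab$group, mean), 3)
#>   control  indolent recurrent
#>     1.189     1.216     1.305
gc <- group_comparison(tab, "corrected_reflectivity")
sprintf("ANOVA F = %.2f, P = %.3g", gc$anova$f, gc$anova$p)
#> "ANOVA F = 19.51, P = 0.000122"
```

Reading the output: this eye's HSS area (369 px in 2 particles) was
selected on the OCTA quadrant at threshold 151; the structural image is
24.1% brighter on that area than overall (ratio 1.241). Across the
16-eye toy cohort the planted group effect is recovered — recurrent eyes
(1.305) sit above indolent (1.216) and control (1.189) — and the omnibus
ANOVA rejects.

For file-based workflows, `write_cohort()` / `run_analyze()` /
`run_report()` read and write TIFF/PNG images and CSV tables
(`<eye>_struct.tif`, `<eye>_octa.tif`, optional `<eye>_faz.png`, plus
`metadata.csv` with columns `eye_id, group, measure_quadrant, quality` and
covariates). The same workflow is scriptable via
`inst/scripts/perivasc <simulate|analyze|stats|report>`.

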