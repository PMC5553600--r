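# lgequant

Infarct-size quantification and core-laboratory reproducibility analysis for
late gadolinium enhancement (LGE) cardiac MR, driven by a synthetic phantom
cohort with a simulated-reader model.

## The problem

LGE infarct size is a trial endpoint, and every way of measuring it —
automated signal-intensity thresholding, manual planimetry, or 17-segment
visual scoring — begins with a human tracing the LV endocardial and
epicardial borders. Two questions dominate multi-laboratory reproducibility:
how much between-reader variability does contour tracing alone inject (it is
present even when the infarct border itself is drawn by a deterministic
algorithm), and how should readers treat intermediate-signal-intensity
("grey") tissue at the infarct rim? `lgequant` builds this measurement
situation from scratch — no patient data — so the mechanisms can be studied
quantitatively with known ground truth.

The package provides:

* a **phantom generator**: annular short-axis LV stacks with a transmural
  infarct sector, a grey border zone, an optional dark no-reflow core,
  bright blood pool, and rician noise, plus exact ground-truth masks and
  contours (`phantom_spec()`, `generate_phantom()`, `cohort_spec()`,
  `generate_cohort()`);
* a **simulated reader**: smooth correlated radial contour perturbations,
  grey-zone interpretation behavior, and a user-correction step
  (`reader_model()`, `perturb_contours()`, `simulate_corrections()`);
* **eight quantification methods**: weighted thresholding
  (weight = min(1, (SI − t)/(F − t)) above t = μ_r + k·σ_r) and FWHM
  (threshold M/2), each with and without user correction; manual planimetry
  with and without 50% grey weighting; 17-segment visual scoring with and
  without signal-intensity weighting (midpoints 13/38/63/88% summed over 17
  segments);
* **reproducibility statistics**: per-patient averaged absolute differences,
  CV = 100·SD(diffs)/mean, ICC(2,1) with F-based CI, Bland–Altman limits of
  agreement, one-way variance components (σ_T², σ_e²), and the two-arm
  sample size n = 2σ²(z_{α/2}+z_β)²/δ² (`run_reproducibility()`,
  `sample_size()`);
* a **pipeline driver** (`run_pipeline()`, YAML-configurable) and NIfTI /
  JSON / CSV interchange.

## Worked example

```r
library(lgequant)

cfg <- pipeline_config(
  cohort = cohort_spec(
    n_patients = 10L, n_readers = 3L,
    phantom_template = phantom_spec(grid = c(80L, 80L, 8L),
      endo_radius_by_slice = seq(24, 2.5, length.out = 8),
      epi_radius_by_slice  = seq(24, 2.5, length.out = 8) + 10),
    master_seed = 42L),
  methods = c("AUTO_SEGMENT", "MANUAL", "MANUAL_ISI", "VISUAL", "VISUAL_ISI"))
out <- run_pipeline(cfg)

head(out$measurements, 5)
#>   patient reader       method percent_lv   mass_g lv_mass_g
#> 1     P01     R1 AUTO_SEGMENT   15.97258 10.83529  67.83683
#> 2     P01     R1       MANUAL   21.01414 14.25532  67.83683
#> 3     P01     R1   MANUAL_ISI   17.12579 11.61759  67.83683
#> 4     P01     R1       VISUAL   18.64706       NA  67.83683
#> 5     P01     R1   VISUAL_ISI   13.42412       NA  67.83683

print(out$report)
#> <lge_repro_report> (percent_lv)
#> method               mean       sd    CV%       ICC [95% CI]  within%
#> AUTO_SEGMENT        22.14     7.27    3.1  0.98 [0.94, 0.99]     2.1
#> MANUAL              29.59    11.76    5.1  0.95 [0.86, 0.99]     5.1
#> MANUAL_ISI          25.38     9.55    2.6  0.99 [0.97, 1.00]     1.1
#> VISUAL              30.11    11.00    5.0  0.95 [0.88, 0.99]     4.6
#> VISUAL_ISI          23.68     8.03    4.6  0.96 [0.89, 0.99]     4.0
#>
#> Sample size per arm:
#>        method delta_3 delta_5 delta_7
#>  AUTO_SEGMENT      99      36      19
#>        MANUAL     258      93      48
#>    MANUAL_ISI     171      62      32
#>        VISUAL     226      82      42
#>    VISUAL_ISI     121      44      23
```

Reading the output: each row of `measurements` is one infarct-size reading
(%LV and grams) by one simulated reader with one method. In the report,
`CV%` is the between-reader coefficient of variation built on per-patient
averaged absolute differences, and `within%` is the share of total variance
attributable to the measurement rather than to true between-patient spread.
Even `AUTO_SEGMENT` — a deterministic border algorithm — has a nonzero CV,
because each reader traced the myocardial contours differently; and the
ISI-weighted variants (`MANUAL_ISI`, `VISUAL_ISI`) have lower CV and lower
mean size than their all-inclusive counterparts. The sample-size table
translates each method's variance into the patients per arm needed to
detect a 3, 5 or 7 %LV absolute reduction in infarct size (α = 0.05,
80% power): better reproducibility means smaller trials.

A single formula check: `sample_size(5, sigma = 10)` returns `63`.

A shell wrapper with `pipeline`, `simulate`, `repro` and `samplesize`
subcommands is installed at `inst/scripts/lgequant.R`.

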