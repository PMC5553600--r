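---
title: "Models and methods: infarct-size quantification and core-laboratory reproducibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: infarct-size quantification and core-laboratory reproducibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Infarct size measured by late gadolinium enhancement (LGE) cardiac MR is a
common efficacy endpoint in acute myocardial infarction trials. Every
quantification method - automated thresholding, manual planimetry, or
17-segment visual scoring - shares one subjective first step: a human traces
the endocardial and epicardial borders of the left ventricle. A second source
of disagreement is tissue of intermediate signal intensity ("grey zone") at
the infarct rim, largely a partial-volume effect, which readers may include,
exclude, or include in part.

`lgequant` reproduces this measurement situation end-to-end with no patient
data: a synthetic short-axis phantom cohort with known ground truth, a
simulated-reader model for contour tracing and grey-zone interpretation,
eight quantification methods, and the reproducibility statistics used to
compare methods across core laboratories (CV, ICC, Bland-Altman, variance
components, trial sample size). The package's aim is mechanistic: to show
that (a) contour tracing alone produces between-reader variability even for
fully automated infarct-border algorithms, and (b) explicit
intermediate-signal-intensity (ISI) weighting improves manual and visual
reproducibility.

# The phantom

Each patient is an annular LV myocardium over `nslices` short-axis slices
(default 10), with per-slice endocardial radii tapering from 24 mm at the
base to 2.5 mm at the apex and a 10 mm wall. The apical-most slice is nearly
closed so the 17-segment apical cap is well defined. The infarct is a
transmural angular sector whose tissue model has four plateaus:

| tissue        | intensity (a.u.)        | default |
|---------------|-------------------------|---------|
| remote (nulled) myocardium | `intensity_remote_mean` | 100 |
| infarct core  | `intensity_infarct_plateau` | 600 |
| grey shell    | midway between remote and core | 350 |
| no-reflow core | 0.4 x remote (dark)    | 40  |
| blood pool    | `intensity_blood_pool`  | 550 |

Noise is rician by default (magnitude MR; gaussian is available for analytic
tests), with `noise_sd = 20`, i.e. a remote SNR of 5 and an
infarct-to-remote CNR of 25 - ordinary LGE image quality. At remote
SNR > 3 the rician mean stays within 5% of the gaussian plateau, which the
test suite asserts.

The grey shell occupies the outer `grey_zone_width` fraction (default 0.4)
of the infarct's radial depth. This is a deliberate simplification: real
intermediate signal arises from partial-volume mixing at all infarct
borders; a radial shell at the rim captures its two analysis-relevant
properties (it borders the infarct, and its intensity is intermediate)
without modelling point-spread physics. The no-reflow zone is the innermost
`no_reflow_fraction` (default 0.15) of the core by area, rendered dark -
microvascular obstruction adjacent to the endocardium.

Ground-truth infarct size counts core and no-reflow voxels at weight 1 and
grey voxels at weight 0.5 (the MANUAL-ISI convention), and is recomputable
from the stored masks exactly; alternative conventions can be derived from
the masks. Papillary muscles and trabeculations are not modelled, so the
exclusion rule for detached papillaries is honored trivially.

Between-patient true sizes are drawn from a normal(20, 10) %LV distribution
truncated to [2, 60], the scale of acute STEMI cohorts (method means of
roughly 17-27 %LV, SDs of 8-13 %LV). The infarct's angular extent is solved
analytically per patient so the drawn size is realized up to rasterization
error (< 1 %LV).

# The simulated reader

Contour tracing error is a smooth periodic gaussian random field over
contour angle: radial displacement with SD `contour_error_sd` (default
1 mm) and squared-exponential angular correlation (length 40 degrees),
plus an optional signed bias. Human tracing errors are spatially smooth -
a reader drifts inside or outside over a stretch of wall - so white vertex
noise would be the wrong model. The 1 mm default is a calibration choice,
not a measured quantity: no quantitative characterization of inter-reader
contour error was available, and 1 mm is under one in-plane voxel, which we
consider the plausible scale for trained readers. Perturbations that would
cross the endocardial and epicardial contours are resampled.

Grey-zone interpretation differs by method, which is the heart of the ISI
mechanism:

* **MANUAL / VISUAL readers** are instructed to include *all* hyperenhanced
  tissue, but the faint outer edge of the grey shell is ambiguous. Each
  reader includes a seeded random fraction u ~ U(0.5, 1) of the shell depth.
  The mean (0.75) makes MANUAL systematically larger than MANUAL-ISI, and
  the spread of u is MANUAL's extra between-reader variance.
* **MANUAL-ISI / VISUAL-ISI readers** apply the fixed 50% rule to their
  perceived shell, whose outer boundary is jittered by
  `grey_boundary_jitter_sd` (default 0.5 mm). The fixed rule leaves much
  less room for disagreement - the self-correcting property the ISI
  protocols are designed to provide.

Blood-pool voxels that fall inside a mis-traced endocardial contour are read
as bright. For the manual and visual readings this happens only within the
infarct's angular sector (a human would not planimeter blood far from the
infarct); the automated algorithms have no such judgment, which is exactly
why the user-correction step exists.

The user-correction step (`AUTO-UC`) is simulated with diligence
`correction_completeness` (default 0.9): with that probability per region,
the true no-reflow zone is added at weight 1 and each connected
false-positive blob of at least 5 voxels (blood pool, artifact) is removed.

# The eight methods

* `AUTO_SEGMENT`: weighted thresholding. Remote myocardium is located
  automatically as the 60-degree angular sector with minimal mean intensity;
  the detection threshold is t = mu_r + 1.8 sigma_r; the fully-infarcted
  plateau F is the mean of supra-threshold intensities at or above their
  0.75 quantile; each voxel above t gets weight min(1, (SI - t)/(F - t)).
  The published description of the commercial weighted algorithm gives the
  weighting principle but not the exact formula, so this linear ramp is a
  declared surrogate; k, the remote window and the plateau quantile are
  configurable.
* `AUTO_FWHM`: full-width at half maximum. The maximum M is the 99th
  percentile of myocardial intensity (robust to hot pixels; the global
  maximum is available), taken per volume; voxels above M/2 are infarct,
  dichotomously. A guard refuses to call infarct when M/2 does not exceed
  remote mean + 2 SD, standing in for the visual pre-screen that separated
  infarct patients from controls.
* `AUTO_UC_SEGMENT`, `AUTO_UC_FWHM`: the same maps after the simulated
  user-correction step.
* `MANUAL`, `MANUAL_ISI`: planimetry emulated by region classification
  (above); MANUAL weights bright, grey and no-reflow at 1; MANUAL-ISI
  weights grey at 0.5.
* `VISUAL`, `VISUAL_ISI`: 17-segment scoring. Extent scores use the 5-point
  scale (0; 1-25%; 26-50%; 51-75%; 76-100%), and VISUAL %LV sums the
  midpoint weights (13, 38, 63, 88%) over 17. VISUAL-ISI multiplies each
  segment's midpoint by an SI weight from the segment's mean hyperenhanced
  intensity relative to the brighter of the brightest infarct voxel and the
  blood pool. The SI weight mapping is not printed anywhere we could adopt
  it from, so it reuses the same midpoint fractions (0.13, 0.38, 0.63,
  0.88) - declared and configurable. No-reflow voxels count as
  hyperenhanced and fully bright.

Segment assignment splits slices into basal/mid/apical thirds by count
(remainders to basal, then mid), with 6 sectors of 60 degrees on basal and
mid rings and 4 sectors of 90 degrees on apical rings, counted from the RV
insertion angle. The apical cap (segment 17) is the apical-most slice when
its cavity area is under 10% of its filled area; otherwise segment 17 stays
unassigned with a warning. These construction details are conventions the
17-segment standard leaves to the implementer.

# Statistics

All statistics run on the measurement table (patient x reader x method):

* **Differences and CV**: per patient, the mean of pairwise absolute
  reader differences (for 3 readers, the mean of the 3 pairs - the
  enumeration is a declared choice); CV = 100 x SD of those per-patient
  values / the method's mean size.
* **ICC**: two-way random-effects, absolute-agreement, single-measurement
  ICC(2,1) with an F-based 95% CI. The ICC form was fixed by us
  (configurable analyses can use the mean squares directly); the test suite
  checks the estimator against direct mean-squares arithmetic to 1e-10.
* **Bland-Altman**: bias, SD, bias +/- 1.96 SD, paired t-test, for every
  reader pair.
* **Variance components**: one-way random-effects moment estimators,
  sigma_e^2 = MS_within, sigma_T^2 = (MS_between - MS_within)/k, and the
  within-patient share of total variance.
* **Sample size**: n = 2 sigma^2 (z_alpha/2 + z_beta)^2 / delta^2 per arm,
  ceiling-rounded, for delta in {3, 5, 7} %LV, alpha = 0.05, beta = 0.2.
  sigma defaults to sqrt(sigma_T^2 + sigma_e^2) (total SD); sigma_T alone is
  a flag, since published analyses are ambiguous about which was used.

# Numerical choices and degenerate inputs

* Myocardial density 1.05 g/mL; voxel depth = slice thickness + gap
  (contiguous coverage), so gapped acquisitions do not under-count mass.
* Rasterization uses the pixel-center rule against polygons in physical mm;
  a tied center counts as inside-epicardium/outside-endocardium. The
  implementation is checked against a brute-force ray-casting oracle.
* The squared-exponential field covariance is factored by eigendecomposition
  with clamped eigenvalues (it is numerically rank-deficient).
* Degenerate inputs produce explicit states rather than garbage: no
  supra-threshold voxel gives a zero map with a "no infarct detected"
  status; a plateau at or below threshold saturates weights at 1 with a
  warning; empty masks warn (mass) or error (sizes); constant measurement
  tables yield zero variance components.

# What the simulations do and do not show

A run of the full battery (`run_pipeline()`) on the default 30-patient,
3-reader cohort reproduces the qualitative structure of multi-laboratory
reproducibility studies: nonzero CV for fully automated border algorithms
driven purely by contour tracing, CV growing with contour error, ISI
variants with lower CV and lower mean size than their inclusive
counterparts, and within-patient variance a small share of total variance.
The phantom is deliberately clean - no papillary muscles, trabeculations,
breathing artifacts, surface-coil shading, or scanner-specific inversion
behavior - so absolute CV/ICC values are more favorable than patient data
would give; only directions and orderings should be compared, not
magnitudes. The reader model is likewise a two-knob abstraction (contour
field + grey-shell handling) of many human behaviors.

Problem sizes used by the test suite are the package's own choices: the
bookkeeping check runs the full battery at 128 x 128 x 10 voxels; the
mechanism checks run 30 patients x 3 readers at 80 x 80 x 8 over five
master seeds; noiseless-recovery sweeps use single phantoms.

# Known limitations

* The weighted-threshold ramp and the display-reference thresholds
  (0.35/0.7 of myocardial max) are surrogates for commercial software and
  SCMR display presets, respectively, honoring their published descriptions
  but not their code.
* The grey shell is radial only; angular partial-volume at the sector edges
  is not modelled.
* Per-volume FWHM maximum (per-slice is configurable but untested against
  any reference).
* The truncated-normal size distribution is the only built-in family.
* Simulated user correction operates on voxel blobs; a human corrects with
  smooth strokes.
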