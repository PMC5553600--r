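Package: lgequant
Title: Infarct Size Quantification and Core-Laboratory Reproducibility for LGE CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates short-axis late gadolinium enhancement (LGE) cardiac MR
    phantom cohorts with ground-truth infarct masks and reader-specific contour
    perturbations, quantifies infarct size with eight methods (weighted
    signal-intensity thresholding, full-width-at-half-maximum, both with and
    without simulated user corrections, manual planimetry with and without
    intermediate-signal-intensity weighting, and 17-segment visual scoring with
    and without signal-intensity weighting), and analyses inter-reader
    reproducibility (coefficient of variation, intraclass correlation,
    Bland-Altman limits of agreement, variance components, and two-arm trial
    sample sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    EBImage,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
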