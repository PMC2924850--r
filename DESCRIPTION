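Package: lvfill
Title: Left Ventricular Diastolic Filling Analysis from Cine CMR Volume Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying left ventricular (LV) diastolic function
    from cine cardiovascular magnetic resonance (CMR) volume-time curves.
    Generates grade-stratified synthetic cohorts of LV filling curves with
    closed-form ground truth, rasterizes them into short-axis cine phantom
    stacks with a stand-in region-growing segmentation, smooths sampled
    curves by periodic Fourier truncation, computes diastolic filling
    indices (peak filling rate, stroke-volume normalized peak filling rate,
    time to peak filling rate, diastolic 80 percent volume recovery, and
    E:A filling-rate profiles), grades diastolic dysfunction from
    echocardiographic criteria, calibrates index cutoffs at a matched
    specificity, and tabulates diagnostic performance as per-grade
    confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
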