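Package: MammoPrep
Title: Context-Adaptive Mammogram Preprocessing and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Triple-way preprocessing for screening mammograms: a
    context/distance-adaptive median filter (CEAMF) whose per-pixel window
    size depends on the distance to detected bright artifacts, Z-score
    intensity normalization, and energy-curve-based context-aware contrast
    enhancement. Also provides a seeded synthetic phantom generator with
    lesion ground-truth masks and five radiographic noise models,
    leakage-safe patient-level cohort splitting with auditing, and a
    segmentation/classification evaluation layer (Dice, IoU, confusion
    metrics, per-case aggregation, percentile bootstrap confidence
    intervals, paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: zlib
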