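Package: walkanchor
Title: Anchoring Wrist-Derived Activity Intensity to Ankle-Detected Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A dual-device free-living accelerometry pipeline that detects
    walking bouts from an ankle-worn accelerometer, classifies wrist-derived
    physical-activity intensity (sedentary, light, MVPA) within those known
    walking bouts, and quantifies how much continuous walking is
    misclassified as sedentary or light behaviour by wrist-only methods.
    Includes gravity-based autocalibration, nonwear detection, average
    vector magnitude (AVM) epoching, step detection and bout segmentation,
    per-participant misclassification statistics (Fisher exact tests with
    Bonferroni correction, a clinical 20-minute threshold, quartile
    stratification with pooled t tests, AVM coefficient of variation), and a
    synthetic dual-site signal generator with ground-truth ledgers covering
    arm-swing suppression, activities-of-daily-living postures,
    parkinsonian tremor, sleep and nonwear, so every stage is testable
    without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
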