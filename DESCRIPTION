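Package: actiward
Title: Accelerometer-Based Activity Monitoring for Elderly Orthopaedic
    Inpatients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to measure and classify in-hospital physical activity of
    elderly patients recovering from proximal femur fracture surgery, from
    tri-axial accelerometry worn at the femur together with consumer step
    counters. Implements signal-vector-magnitude (SVM) epoch processing with
    band-pass filtering and wear-time detection, population-specific activity
    threshold calibration (90th percentile of inactive-period epochs),
    four-level activity categorisation on the percent-active-minutes and
    mean-SVM scales via published boundaries or one-dimensional discriminant
    analysis, step-counter validation (event-detection sensitivity and
    specificity, steps-per-minute discrimination, regression against counted
    steps), and longitudinal recovery comparisons against the Barthel-20 and
    EQ-5D-3L clinical scores. A synthetic cohort generator with configurable
    event-duration, activity-level, device-error and clinical-score models
    stands in for ward recordings so the whole pipeline is testable offline.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
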