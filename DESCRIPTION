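Package: accelcohort
Title: Accelerometer Data Reduction and Comparative Analysis for Youth Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for pooled youth accelerometry studies: reads
    minute-epoch (or finer) ActiGraph-style count series, reintegrates them
    to 60 s epochs, detects device non-wear (60 min of consecutive zeros
    tolerating 2 min non-zero interruptions), applies wear-window and
    valid-day rules, classifies minute intensity with the Evenson
    cut-points, and summarises activity per day and per
    participant-timepoint (counts per minute, intensity composition, strict
    and liberal 60-min MVPA guideline adherence). Adds IOTF weight-status
    classification and sex-by-ageband BMI standardisation, season
    assignment with hemisphere inversion, cluster-robust adjusted linear
    regression, within-country outcome standardisation, and
    DerSimonian-Laird random-effects meta-analysis across countries. A
    synthetic cohort generator with a known truth manifest supports
    parameter-recovery experiments for the sex gap, age-related decline and
    weight-status deficit in activity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    data.table,
    sandwich,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
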