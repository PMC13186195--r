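Package: glp1traj
Title: Weight Trajectories After the Last GLP-1 Receptor Agonist Prescription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort phenotyping and weight-trajectory analysis anchored on the
    last semaglutide or tirzepatide prescription in electronic-health-record
    extracts. Builds discontinuation cohorts from prescription timelines
    (persistence runs, washout gaps, index dates, baseline weights), computes
    percent-weight-change trajectories in 30-day bins with two-stage
    (patient-median, then cohort mean) aggregation and confidence intervals,
    classifies weight regain against a configurable threshold, scores
    maintenance-dose attainment per brand, rolls note-level extracted events up
    to patient-level indicators, and compares outcome groups with chi-square
    tests. Ships a seeded synthetic-EHR generator so the whole pipeline is
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
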