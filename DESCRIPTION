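Package: gttade
Title: Global Trigger Tool Screening for Adverse Drug Events in Elderly Inpatients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Global Trigger Tool (GTT) pipeline for detecting adverse drug
    events (ADEs) in elderly inpatients from tabular electronic-health-record
    extracts. Implements a 36-rule trigger registry (17 laboratory, 10
    treatment, 8 clinical-symptom and 1 intervention trigger) evaluated over
    admissions, medication administrations, laboratory results and clinical
    events; Naranjo causality scoring and CTCAE severity grading of reviewer
    adjudications; per-trigger and overall positive predictive value, ADE
    rates per 100 admissions and per 1,000 patient-days, onset-time,
    organ-system and severity distributions; rank-sum/chi-square group
    comparisons and binary logistic regression of ADE risk factors; and a
    seeded synthetic-cohort generator with planted, ground-truth trigger
    conditions so the whole pipeline is testable without real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
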