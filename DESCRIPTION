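Package: mcvrisk
Title: Encounter-Level Maternal Cardiovascular Risk Screening and Lead-Time Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based screening of longitudinal obstetric electronic health
    record (EHR) encounter streams for maternal cardiovascular risk. Each
    encounter is evaluated against clinician-defined vital-sign, symptom and
    medical-history thresholds and classified as standard or red-flag
    (high-risk); risk profiles are linked to the first recorded diagnosis or
    intervention of nine tracked cardiovascular pregnancy conditions
    (preeclampsia, eclampsia, cardiomyopathy, myocardial infarction, heart
    failure, acute kidney disease/failure, cerebral infarction, pulmonary
    embolism, venous thromboembolism, HELLP) within the same pregnancy
    episode, yielding signed lead-time deltas. Includes a seeded synthetic
    obstetric cohort generator calibrated to published demographic,
    prevalence and lead-time marginals, CONSORT-style inclusion/exclusion
    flow accounting, and study-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
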