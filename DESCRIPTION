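Package: mammorisk
Title: Long-Term Calibration of Breast Cancer Risk Models with Mammographic Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Absolute 10-year invasive breast cancer risk from classic
    questionnaire risk factors combined with BI-RADS mammographic density,
    projected against baseline incidence with competing mortality, together
    with a long-term calibration-validation toolkit: expected events from
    predicted cumulative risk, exact Poisson observed/expected ratios,
    risk-stratum tables, Kaplan-Meier cumulative-risk curves, decile hazard
    ratios, a time-varying calibration coefficient from a proportional-hazards
    model with a yearly predicted-hazard covariate, likelihood-ratio
    information beyond age, and risk reclassification. A synthetic
    screening-cohort simulator with tunable miscalibration reproduces the
    statistical structure these methods assume, so the whole pipeline is
    testable without registry access.
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
    survival,
    stats,
    utils,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
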