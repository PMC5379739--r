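Package: adherekit
Title: Antiretroviral Adherence Measures and Virological Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements six antiretroviral-therapy adherence estimators
    (3-day self-report, clinic-based pill count, pharmacy-refill average,
    pharmacy-refill gaps via medication-free days, efavirenz therapeutic
    drug monitoring, and electronic adherence monitoring with dead-battery
    censoring), landmark-window derivation of virological failure and
    HIV-1 drug-resistance outcomes, logistic regression models reporting
    odds ratios per 10 percent adherence increase, ROC/AUC estimation with
    DeLong confidence intervals and paired nonparametric AUC comparison,
    and a seeded synthetic cohort generator that emulates the measurement
    processes (biased self-report, pill dumping, early refills, pocket
    dosing, dead-battery censoring) so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
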