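Package: tdmattain
Title: Beta-Lactam TDM Target Attainment, Therapy Adjustment and Outcome
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for beta-lactam therapeutic drug monitoring (TDM) in
    critically ill patients: reconstruction of individual steady-state
    one-compartment kinetics from peak/trough (or random) total plasma
    concentrations, free-fraction correction, PK/PD target attainment
    (fT>MIC, fT>n*MIC, fCmin/MIC), effective-MIC resolution from isolates
    and breakpoint fallbacks, classification and recommendation of therapy
    adjustments, logistic-regression and Kaplan-Meier/log-rank outcome
    analyses, and a calibrated synthetic ICU cohort generator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
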