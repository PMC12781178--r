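Package: hrvrisk
Title: Heart Rate Variability Decision Support for Deterioration Risk in
    Suspected Infection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for heart rate variability (HRV) based
    prognostication in emergency department patients with suspected infection:
    lead-II ECG and RR-interval input/output, R-peak detection with quality and
    rhythm gating, a nonlinear HRV metric panel (detrended fluctuation analysis,
    multiscale and fuzzy entropy, Lomb-Scargle power-law fit, heart rate
    asymmetry), a five-model lab-availability-driven logistic risk cascade
    producing the probability of clinical deterioration within 72 hours, SIRS
    eligibility screening, outcome labelling, structured decision-support
    reports, and a synthetic-data generator (RR series, template ECG, patient
    cohorts) that makes every stage testable without patient data. Shipped model
    coefficients are demonstration fits on synthetic cohorts and carry no
    clinical validity.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
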