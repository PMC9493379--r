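Package: ntcpval
Title: External Validation and Closed-Testing Updating of Logistic NTCP Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating logistic normal tissue
    complication probability (NTCP) models on independent patient cohorts
    and for updating them with the closed testing procedure over the
    four-level calibration hierarchy (original model, re-calibration in
    the large, logistic recalibration, model revision). Ships the national
    indication protocol (NIPP) grade II-IV six-month dysphagia model for
    head and neck radiotherapy, computes discrimination (AUC with DeLong
    or bootstrap confidence intervals, sensitivity, specificity) and
    calibration (Brier score, Hosmer-Lemeshow test, flexible calibration
    curves, Emax/Eavg/E90) metrics, estimates delta-NTCP between photon
    and proton plans, and generates synthetic cohorts with configurable
    dose marginals, correlation and miscalibration so every part of the
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    jsonlite,
    readr,
    ggplot2,
    pROC,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
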