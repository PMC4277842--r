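Package: icuval
Title: External Validation of ICU Mortality Risk-Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating logistic risk-prediction models
    for acute hospital mortality in critical care. Implements an auditable
    admission exclusion cascade, data harmonisation (location recoding,
    regression imputation of physiology extremes, a sedation assumption and
    five-tier hierarchical diagnosis mapping), a generic logistic risk-model
    engine driven by user-supplied coefficient tables, and a full battery of
    discrimination, calibration and accuracy statistics: the c index with
    DeLong standard errors and paired model comparison, the Hosmer-Lemeshow
    test in risk deciles, Cox calibration regression, Brier score, Shapiro's
    R and their scaled R-squared analogues, and Wilson score intervals.
    A seeded synthetic-cohort generator emulating a realistic critical-care
    case mix makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
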