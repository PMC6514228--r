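Package: gradedCAT
Title: Graded Response Model Item Banking and Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating computerized adaptive tests (CAT)
    based on Samejima's graded response model (GRM) for five-category ordinal
    items. Ships the calibrated 59-item internet-addiction (CAT-IA) item bank,
    reads and validates GRM item banks, calibrates item parameters by marginal
    maximum likelihood (EM), screens candidate item pools for unidimensionality,
    local dependence (Yen's Q3), monotonicity (Mokken scalability), item fit
    (S-X2), differential item functioning (ordinal logistic regression with
    McFadden pseudo-R2 change) and low discrimination, simulates adaptive
    administrations with maximum-information item selection and expected a
    posteriori scoring under standard-error stopping rules, and summarizes
    measurement precision (conditional bias/MAE/RMSE/SEE), marginal reliability,
    item savings, concurrent validity and ROC-based predictive validity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
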