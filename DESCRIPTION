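Package: symrules
Title: Association Rule Mining of Clinical Symptom Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing co-occurrence of binary clinical symptoms
    in case-control style cohorts. Reads and validates binary cohort tables
    (with token dialects such as Yes/No), dichotomizes continuous covariates
    at ROC-selected cutoffs, screens symptoms against an outcome with 2x2
    contingency tables and Pearson chi-square tests, mines outcome-targeted
    association rules with a from-scratch level-wise Apriori algorithm
    scored by support, confidence and lift, and renders order-stratified
    rule tables. Includes a conditional-independence synthetic cohort
    generator and a deterministic fixture cohort for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
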