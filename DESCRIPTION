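Package: painbps
Title: Biopsychosocial Biomarker Pipelines for Chronic Pain Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating multimodal biomarker pipelines
    for pain-associated medical conditions on tabular cohort data. Implements
    a synthetic cohort generator with planted effects, fold-wise regression
    deconfounding, repeated nested cross-validated ridge logistic
    classification with balanced class weights, structure-coefficient
    encoding maps and composite signatures with density thresholding and
    permutation-null evaluation, deviance-explained partitioning between
    biological and psychosocial prediction sources, risk-quintile odds-ratio
    synergy grids, Kaplan-Meier/Cox survival contrasts of baseline risk
    groups, medication-exclusion sensitivity analyses, and a bootstrap path
    model linking risks through diagnosis onset to pain outcomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    survival,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
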