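Package: pacsense
Title: Clinical and Genomic Prediction of Paclitaxel Benefit in Advanced
    Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study whether patients with advanced gastric cancer
    benefit from second-line paclitaxel-based chemotherapy, integrating
    binary clinical covariates with panel-sequencing pathogenic variants.
    Provides a seeded synthetic-cohort generator with planted (optionally
    non-additive) benefit signals and calibrated exponential survival
    endpoints; progression-free-survival threshold labelling and
    outcome-stratified splitting; four classifier back-ends behind one
    fit/predict contract, including a from-scratch variant-set embedding
    neural network; ROC/AUROC machinery with stratified bootstrap
    confidence intervals; Kaplan-Meier estimation and the log-rank test
    implemented from first principles; and an end-to-end, fully seeded
    experiment runner with report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
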