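Package: pahphen
Title: Claims-Based Machine-Learning Identification of Pulmonary Arterial Hypertension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computable-phenotype pipeline for finding pulmonary arterial
    hypertension (PAH) patients in coded electronic medical record (EMR) data.
    Provides a synthetic longitudinal EMR generator with a planted rare PAH
    subpopulation and realistic confounder strata; a three-category screening
    tool over ICD, CPT and medication lexicons; a hemodynamic chart-review
    oracle implementing the World Symposium on Pulmonary Hypertension (WSPH)
    pre-capillary criteria; a strength/persistence/durability feature calculus
    over longitudinal code mentions; random-forest, gradient-boosting and
    elastic-net classifiers tuned by Gaussian-process Bayesian optimization
    over repeated stratified cross-validation; and a multi-stage
    development/refinement/final-cohort training procedure with split-cohort
    internal validation and diagnostic test characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    lhs,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
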