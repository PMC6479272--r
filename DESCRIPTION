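Package: ovasig
Title: Multigene Signature Profiling and Penalized Cox Prognostic Modeling
    for Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sphingolipid/lysophosphatidate/immune
    multigene qPCR signatures in epithelial ovarian cancer cohorts:
    delta-delta-Ct normalisation against housekeeping genes, chained-equations
    imputation, gene-gene correlation and hierarchical-clustering based
    immune-low/high patient stratification, ridge and lasso penalised Cox and
    logistic models with nested leave-one-out cross-validation, model
    validation by the concordance index, the Schemper-Henderson proportion of
    explained variation, added-value testing and Kaplan-Meier quartile risk
    groups, signature-similarity ranking against expression compendia, and a
    synthetic-cohort generator emulating the statistical structure of such
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
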