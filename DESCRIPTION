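Package: immunage
Title: Immune Aging Clocks and Age-Corrected Immunophenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age-structured immunophenotyping cohorts:
    smoothing-spline trajectory modeling and shape clustering of immune
    phenotypes over age, a two-stage random-lasso "immunological age"
    estimator with a cross-validated importance cutoff, weighted
    distributional regression (GAMLSS-style, Box-Cox t or normal families)
    producing per-subject age-corrected centiles, rank-based multi-group
    disease association testing with Benjamini-Hochberg correction, and a
    PCA plus logistic-regression disease classifier evaluated over repeated
    train-test splits. Includes a synthetic cohort generator that emulates
    the statistical structure of cross-sectional flow-cytometry cohorts
    (bimodal age distributions, four canonical age-trajectory shapes,
    right-skewed intensity readouts, group-dependent shifts) so that every
    stage of the pipeline can be exercised and calibrated without access to
    restricted subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    glmnet,
    pROC,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mgcv,
    withr
Config/testthat/edition: 3
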