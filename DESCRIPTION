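Package: medilmm
Title: Mediation Analysis for Longitudinal High-Dimensional Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural-equation mediation analysis for repeated-measures
    microbiome studies with a continuous clinical outcome. Direct and
    taxon-specific indirect effects of a clinical exposure are estimated with a
    debiased-lasso estimator for fixed effects in high-dimensional linear mixed
    models (covariance-proxy whitening, scaled lasso, nodewise correction
    scores), REML random-intercept mediator models, and product-of-coefficients
    effect composition; inference uses a cluster-level non-parametric bootstrap
    with BCa confidence intervals and Benjamini-Hochberg adjustment. A
    community-level single-mediator mode treats genus-level alpha-diversity
    indices as the mediator, and a synthetic-data generator produces clustered
    longitudinal compositional datasets with known effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    parallel,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    lme4,
    biomformat,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
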