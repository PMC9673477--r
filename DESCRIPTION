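Package: gsbench
Title: Benchmarking Genomic Phenotype Prediction with Simulated Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking pipeline for genomic selection. Simulates
    quantitative phenotypes on SNP genotype matrices under a linear mixed
    model with a polygenic background, controlled heritability, additive
    and epistatic fixed effects and optionally skewed noise. Provides a
    roster of prediction models behind a uniform contract (RR-BLUP fitted
    by restricted maximum likelihood, Bayes A/B/C Gibbs samplers, LASSO,
    Elastic Net, support vector regression, random forest, gradient
    boosting, and three neural-network architectures), evaluates them with
    stratified nested cross-validation and sequential hyperparameter
    optimization with percentile pruning, and scores fold-aggregated
    feature importances against the simulated causal and background
    markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    glmnet,
    e1071,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
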