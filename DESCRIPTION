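Package: nbglobal
Title: Global Score Tests for Overdispersed Count Responses and
    High-Dimensional Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Omnibus (global) score tests for association between a
    count response, such as the RNA-Seq expression of a single gene, and
    a potentially high-dimensional set of covariates (SNP dosages, copy
    numbers, methylation values). The response is modelled as negative
    binomial with a free dispersion parameter (Poisson as the boundary
    case), covariate effects are treated as random with a common variance
    component, and inference is by permutation, optionally stratified to
    respect known sample groupings. Includes exact decompositions of the
    test statistic into per-sample and per-covariate contributions, a
    control-variates estimator that sharpens permutation p-values, a
    standardised-sum joint test across multiple molecular profiles, a
    synthetic-data generator with correlated genotype blocks, power and
    calibration studies, and a genome-wide scan driver with window-based
    covariate selection and false-discovery-rate correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
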