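Package: micrand
Title: Randomization-Based Causal Inference for Matched Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design-stage constrained pair matching and Fisherian
    randomization inference for assessing effects of binary environmental
    exposures on gut microbiome count data. Provides a synthetic paired-cohort
    generator with known potential outcomes, maximum bipartite matching under
    covariate proximity thresholds with balance diagnostics, within-pair
    permutation engines with a fully randomization-based min-p multiple-testing
    adjustment, and a five-level test-statistic suite: alpha-diversity
    meta-regression coefficients, beta-diversity kernel score tests over
    UniFrac/Aitchison/Jaccard/Gower distances, a high-dimensional compositional
    mean statistic, reference-normalized differential abundance, and sparse
    partial-correlation network estimation with differential-edge tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
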