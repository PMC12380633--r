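Package: spatdecay
Title: Maximum-Likelihood Estimation of Distance-Dependent Neuronal Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the spatial decay of functional connectivity in large
    neuronal populations directly from spike rasters and somatic coordinates,
    without reconstructing pairwise connections. Implements a maximum-likelihood
    estimator of a global distance-decay parameter for several kernel families
    (exponential, half-Gaussian, linear, inverse-square, lognormal), a full
    three-parameter spatial generalized linear model with analytic gradients,
    comparator estimators based on transfer entropy, point-process Granger
    causality and spike-count correlations, generative simulators (linear
    Poisson network and a spatially embedded Izhikevich network), mean-field
    predictions linking spatial decay to pairwise correlations, and a
    kernel-identification procedure by maximized log-likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
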