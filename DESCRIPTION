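Package: dgmnet
Title: Dynamic Graphical Models for Directed Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates directed, possibly cyclic functional-connectivity
    networks from multivariate time series using dynamic graphical models:
    each node is modelled by a conjugate dynamic linear regression on
    candidate parent nodes with a discount-factor-controlled random walk on
    the coefficients, the closed-form log model evidence drives an
    exhaustive per-node parent-set search, and reciprocal edges can be
    pruned by Bayes-factor model comparison. Also provides binomial
    edge-consistency tests across subjects with FDR correction, Patel's
    kappa/tau conditional-dependence baseline with a group permutation
    test, and a balloon-model network simulator with per-node hemodynamic
    transit-time manipulation for validation studies.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'dgmnet-package.R'
    'dlm.R'
    'group-inference.R'
    'netsim.R'
    'network-search.R'
    'patel.R'
    'timeseries-io.R'
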