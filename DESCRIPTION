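Package: scads
Title: Sparse Common and Distinctive Simultaneous Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simultaneous component analysis of multi-block data (several
    groups of variables measured on the same observation units) with
    component weights that are constrained to zero outside a chosen subset
    of blocks (common versus distinctive components) and penalized with
    lasso and ridge terms for automated variable selection. Provides the
    penalized alternating least-squares estimator with coordinate-descent
    weight updates, sparse PCA as the unconstrained special case,
    enumeration of all common/distinctive weight structures, model
    selection by Eigenvector-method cross-validation (MPRESS) with the
    one-standard-error rule, a seeded multi-block data generator, recovery
    metrics (Tucker congruence, zero/nonzero classification rate, variance
    accounted for), and runners for the parameter-recovery and
    structure-selection simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
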