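Package: bifactorsim
Title: Monte Carlo Study of Confirmatory Bifactor Models with Ignored
    Cross-Loadings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the consequences of fixing non-zero cross-loadings
    to zero in confirmatory bifactor models. Provides an orthogonal bifactor
    population model with configurable group-factor loadings and
    cross-loadings, multivariate-normal data generation, normal-theory
    maximum-likelihood estimation of correct and misspecified model variants
    with nonconvergence and Heywood-case detection, sample and population
    goodness-of-fit indices (RMSEA, CFI, GFI, SRMR, the asymptotically
    unbiased SRMR, and the communality-corrected SRMR ratio with its
    cutoffs), RMSD parameter-recovery metrics, and a study engine that runs
    the full factorial simulation grid and summarises it with a factorial
    ANOVA meta-model and partial eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    jsonlite,
    optparse
Config/testthat/edition: 3
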