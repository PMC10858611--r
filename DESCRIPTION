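Package: rfqt
Title: Random Forests of Q Trees for Heterogeneous Causal Effects in
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and estimates heterogeneous causal effects in
    instrumental-variable (Mendelian randomization) analyses with
    high-dimensional covariates. Implements collider-robust
    stratification on a covariate by the doubly-ranked and residual
    methods, stratum-specific instrumental-variable estimation with
    Cochran's Q heterogeneity statistic, recursive Q-tree partitioning
    and bootstrap-aggregated random forests of Q trees with out-of-bag
    prediction, permutation variable importance, permutation tests of
    effect heterogeneity, and Rubin's-rules pooling of stratum-specific
    estimates with trend tests. Includes a simulator generating data
    with instrument, exposure, outcome and candidate covariates under
    configurable collider structure and effect-modification strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    metafor,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
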