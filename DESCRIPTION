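Package: covsel
Title: Backward Covariate Selection for RNA-Seq Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects a common set of covariates for gene-wise negative
    binomial log-linear models of RNA-seq read counts by backward
    elimination, removing at each step the covariate whose per-gene
    p-value distribution looks least relevant (fewest p-values below
    0.05, or a Grenander-Kolmogorov-Smirnov distance from uniformity)
    and choosing the model in the elimination sequence that maximizes
    the number of q-value discoveries for the factor of primary
    interest. Testing uses quasi-likelihood F-statistics with
    empirical-Bayes shrinkage of gene-specific quasi-dispersions,
    Storey q-values with a histogram-based estimate of the number of
    true nulls, and upper-quantile normalization offsets. Includes a
    negative binomial simulation framework with three covariate-
    structure scenarios (common relevant set, gene-specific nested
    sets, and a primary-factor-confounded continuous covariate) for
    benchmarking false discovery rate, power, and partial AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    limma,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
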