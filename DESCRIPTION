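Package: cmrf
Title: Copula-Based Multivariate Random Forests for Multi-Output Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Multivariate random forests for jointly predicting several
    real-valued responses (for example sensitivities of a cell line to a
    set of related drugs) from a common feature matrix. Regression-tree
    node splits can be scored by the classical sum of squared errors, by
    a Mahalanobis (covariance-normalised) cost, or by a copula-based cost
    that penalises splits whose child nodes distort the rank-dependence
    structure of the training responses. Includes empirical-copula
    estimation on a grid, Frechet-Hoeffding bound integrals, Clayton
    copula sampling, two data-driven procedures (grid search and
    Pareto-frontier slope fitting) for choosing the weight that balances
    the two components of the copula cost, selection-frequency variable
    importance, k-fold cross-validation with Pearson/MAE/NRMSE scoring,
    synthetic data generators with controllable response dependence, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
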