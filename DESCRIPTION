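Package: consvm
Title: Invariant Linear Support Vector Machines for Molecular Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and analysis of structurally constrained linear
    support vector machines for molecular profile classification.
    Implements the offset-free, contrast, offset-free-contrast and
    pairwise-comparison subclasses of linear classifiers, whose structural
    constraints guarantee invariance against global scaling, global
    transition (shift), affine transformations and arbitrary feature-wise
    strictly increasing transformations of the input profiles. Provides
    L2- and L1-regularized soft-margin solvers under these constraints,
    empirical invariance verification, brute-force Vapnik-Chervonenkis
    dimension checks via shattering feasibility, a two-class Gaussian
    benchmark generator with sample-wise and class-wise noise regimes,
    and tidy experiment harnesses including repeated stratified
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quadprog,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
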