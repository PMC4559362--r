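Package: thsurr
Title: Regression Surrogates for a Kinetic Model of CD4+ T Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates the steady-state cytokine input-output map of a reduced
    Hill-kinetics model of CD4+ T helper cell differentiation (Th1/Th17/Treg)
    with four regression surrogate families: ordinary least squares, a
    back-propagation multilayer perceptron, epsilon-insensitive support vector
    regression with a radial kernel, and a random forest of regression trees.
    Provides full-factorial steady-state dataset generation, min-max
    normalization, multiplicative output noise injection, train/test splitting,
    hyperparameter scans, k-fold cross-validation, noise-robustness and runtime
    benchmarking, and directional validation against published in vitro
    cytokine stimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
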