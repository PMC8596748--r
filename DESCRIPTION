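Package: abdetect
Title: Simulation and Automated Effect Detection for Single-Case AB Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates single-case AB-design graphs with controlled phase
    lengths, first-order autocorrelation, trend, variability, and effect
    size, and detects treatment effects with three automated methods: the
    conservative dual-criteria rule, a hinge-loss stochastic-gradient linear
    classifier, and a radial-basis support vector classifier trained on
    eight per-graph features. Includes an evaluation harness computing
    accuracy, pairwise agreement, Type I error rate, and power with binomial
    confidence intervals, overall and stratified by graph characteristic,
    plus CSV/PDF input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
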