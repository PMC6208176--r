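Package: emofuse
Title: EEG Emotion Recognition by Evidence Fusion of Local Feature Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quadrant-based emotion recognition from multichannel
    EEG. Implements second-order blind identification (SOBI) for source
    separation and channel-activity mapping, threshold-based selection of
    emotional channels, nine nonlinear phase-space and entropy features
    (correlation dimension, Higuchi fractal dimension, largest Lyapunov
    exponent, sample entropy, recurrence quantification measures and
    differential entropy), local subset feature selection via Monte-Carlo
    feature-tree search, and fusion of two multilayer-perceptron classifiers
    with Dempster-Shafer evidence theory. Includes a synthetic EEG generator
    with planted class structure, stratified cross-validation, confusion and
    confidence matrices, and a staged command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
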