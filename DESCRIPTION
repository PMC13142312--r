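Package: pursuitnet
Title: Recurrent Network Models of Predictive Pursuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of recurrent neural network (RNN)
    agents trained to pursue a moving target in a bounded arena. Provides
    generators for random and characteristic (stereotyped) target
    trajectories under reflective or periodic boundaries, a leaky
    discrete-time RNN agent with rank-constrained recurrent connectivity,
    supervised training by backpropagation through time under final- or
    mean-distance losses, a reactive (non-predictive) pursuit baseline,
    behavioral predictivity metrics (shortcut metric, normalized trajectory
    deviation, Kolmogorov-Smirnov and Wasserstein comparisons, waiting
    detection), and representational analyses (egocentric target tuning and
    mean resultant length, egocentric-target-unit classification with
    shuffle nulls, unit ablation curves, PCA and participation-ratio
    dimensionality, linear decoding of egocentric and allocentric task
    features).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
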