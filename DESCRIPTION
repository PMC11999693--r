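Package: creditlearn
Title: Credit Assignment in Contingent Learning: Behavioral Models and
    Multivariate Neural Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-condition contingent-learning task in which
    choice-outcome transitions are either direct or punctuated by an interim
    decision, models behavior with a Bayesian volatility learner (grid
    integration over reward probability, volatility and volatility-change
    scale) and a value-caching reinforcement-learning alternative, fits
    learner parameters by likelihood maximization with random-walk MCMC,
    quantifies credit assignment with lagged choice-by-outcome logistic
    regression, and runs searchlight decoding, information-connectivity and
    threshold-free cluster enhancement (TFCE) group analyses on synthetic
    trial-by-voxel pattern cohorts that embed causal-choice, pending-choice
    and stimulus-identity signals with controllable amplitude, noise and
    cross-region fidelity coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
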