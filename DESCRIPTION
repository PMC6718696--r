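Package: liquidrl
Title: Reinforcement Learning with Liquid State Machine Reservoirs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Q-learning on top of a liquid state machine: a fixed, sparsely and
    randomly connected reservoir of excitatory and inhibitory leaky
    integrate-and-fire neurons transforms environment states, delivered as
    Poisson spike trains, into high-dimensional normalized firing-rate
    activations that a small trainable readout maps to action values. Provides
    balanced excitatory-inhibitory connectivity initialization with eigenvalue
    stability diagnostics, rate/one-hot/signed/binary-map state encoders,
    experience-replay Q-learning with an epsilon-greedy policy and RMSProp,
    self-contained cartpole (full and partial observation) and grid-Pacman
    environments, and reproducible multi-seed experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
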