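Package: eventgaze
Title: Event-Predictive Inference and Goal-Anticipatory Gaze in a Simulated Infant Observer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the development of goal-predictive gaze in an observer of
    simple two-entity action events (still, random motion, reach, transport).
    Learns probabilistic event schemata -- start, dynamics and end densities per
    event, each a small Gaussian density network -- from labelled event
    sequences, infers the currently unfolding event with a recursive Bayesian
    filter, selects gaze fixations by minimising expected free energy
    (anticipated observation entropy within the current event and at the next
    event boundary), and retrospectively adapts an actor-specific agency
    estimate by gradient descent on the negative sequence log-likelihood
    (coherence optimisation). Includes the full scenario simulator with
    gaze-dependent sensory noise, a developmental training curriculum with
    interleaved test phases, and metric extraction (first patient fixation,
    gaze-arrival delta).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
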