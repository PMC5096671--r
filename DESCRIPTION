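Package: rotdyn
Title: Rotational Dynamics and Covariance-Matched Permutation Tests for
    Neural Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of motor-cortex population activity
    during center-out reaching. Provides generative models of
    representational (cosine velocity-tuned, with variable neuron-kinematic
    latencies) and dynamical (two-oscillator basis) populations, jPCA
    dimensionality reduction with skew-symmetric dynamics fitting and
    rotation metrics, a covariance-matched permutation test (CMPT) that asks
    whether rotational structure depends uniquely on the neuron-to-condition
    assignment, a continuous-rate recurrent network trained to produce reach
    velocity profiles, and classical representational read-outs (preferred
    directions, population vector, lagged velocity regression, tuning
    stability).
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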