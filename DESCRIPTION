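Package: compsyn
Title: Competing Binary Synapses: Lattice Simulation, Mean-Field Dynamics
    and Adaptation Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional network of binary (strong/weak)
    plastic synapses whose state updates are driven by competition between
    neighbouring synapses, together with the mean-field effective dynamics
    of the strong-synapse fraction. Provides the single-update outcome
    probabilities, the drift equation with its stable fixed point and
    exponential relaxation time, a seeded stochastic lattice Monte-Carlo
    oracle, signal perturbations of the activation parameters, the
    de-adaptation, downscaling and anterograde-interference protocols with
    saturation-based timescale measurement, and two-dimensional
    learning-versus-forgetting phase maps computed by both analytic and
    numeric routes.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
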