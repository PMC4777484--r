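Package: frachh
Title: Fractional-Order Hodgkin-Huxley Neuron Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a Hodgkin-Huxley neuron in which one
    gating variable (n, m, or h) evolves under a Caputo fractional derivative
    of order eta <= 1, giving the corresponding conductance power-law,
    history-dependent kinetics. Provides the classic fourth-order Runge-Kutta
    baseline, the L1 discretization of the Caputo derivative with its memory
    trace, the Mittag-Leffler analytic solution of the linearized gate
    equation, voltage-clamp characterization with dual-exponential fits,
    spike-shape metrics (half-width, current and voltage thresholds),
    phase-plane current analysis, and an automated classifier of the emergent
    spiking patterns (resting, phasic, tonic, mixed-mode oscillations,
    square-wave bursting, pseudo-plateau bursting) over an input-current by
    fractional-order grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
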