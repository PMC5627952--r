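Package: stpphase
Title: Phase of Postsynaptic Spiking Through Depressing Stochastic Synapses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a feed-forward synaptic pathway with short-term
    depression driven by sinusoidally rate-modulated Poisson spike trains,
    and quantifies the phase lead of postsynaptic spiking relative to the
    input modulation. Vesicle release and replenishment at a fixed pool of
    release sites partitioned into active zones is simulated with an
    event-driven stochastic algorithm; the postsynaptic membrane is a
    single-compartment Hodgkin-Huxley or leaky integrate-and-fire neuron
    driven by difference-of-exponentials AMPA conductances. Phase is
    estimated from peristimulus time histograms via the circular order
    parameter. A companion analytical module solves the vesicle-availability
    ODE, its closed-form phase approximation, the quantized release-rate
    phase surface over active-zone number and modulation frequency, and the
    depression-driven phase resonance frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
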