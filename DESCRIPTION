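Package: memfhn
Title: Synchronization in Adaptive Networks of Memristive FitzHugh-Nagumo Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation pipeline for complete and phase synchronization in
    time-varying networks of memristive FitzHugh-Nagumo neurons. Synaptic
    weights evolve under a depression-dominated, nearest-spike-pair,
    multiplicative spike-timing-dependent plasticity (STDP) rule, and the
    directed Watts-Strogatz wiring evolves under homeostatic structural
    plasticity (HSP) rewiring rules that preserve the small-world or random
    character of the network. Provides a compiled fourth-order Runge-Kutta
    integrator for the delayed coupled system, spike detection, the
    synchronization error E, the Kuramoto order parameter R computed from
    interpolated spike phases, the mean synaptic weight G, interspike-interval
    statistics, Monte Carlo basin-stability estimation, and parameter-plane
    sweep drivers with reproducible seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
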