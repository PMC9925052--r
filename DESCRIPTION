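Package: spikeroute
Title: Spike-Sequence Propagation and Routing in Biologically Constrained
    Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-spike-triggered activity
    propagation in spatially embedded recurrent networks of adaptive
    exponential integrate-and-fire neurons with lognormally distributed
    synaptic conductances, modelled on the three-layered turtle visual
    cortex. Provides the network generator (distance-dependent Gaussian
    connectivity on a torus, truncated-lognormal weights), a clock-driven
    conductance-based simulation engine with single-spike trigger
    protocols, statistical detection of reliably activated 'follower'
    neurons against an exact Poisson-difference null, spike-rank entropy
    and spatial centre-of-mass measures, spike-transfer graph and motif
    analyses, k-modes decomposition of followers into sub-networks with
    gate identification and gating maps, multi-trigger follower
    classification, the parameter-fitting procedures that constrain the
    model (membrane least squares, truncated-lognormal fits, a
    strong-connection bootstrap), and synthetic-data generators that
    emulate the electrophysiological inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
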