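Package: synfc
Title: Spiking-Network Simulation and Inference of Synaptic Structure from
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates recurrent networks of Izhikevich neurons with
    heterogeneous conduction delays and spike timing-dependent plasticity,
    and infers their synaptic structure from spiking activity. Static
    functional connectivity (normalized cross-correlation and
    cross-covariance, transfer entropy and its higher-order word-embedding
    variant) is swept over candidate delays to recover synapse presence,
    sign and communication delay; dynamic functional connectivity in
    non-overlapping sliding windows, evaluated at the statically inferred
    delay, tracks the temporal evolution of synaptic weights and is scored
    against the simulator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
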