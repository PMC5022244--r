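Package: synapsim
Title: Synapse-Centric Mapping and Simulation of Spiking Neural Networks
    on Many-Core Neuromorphic Hardware
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software simulator for the synapse-centric approach to mapping
    spiking neural networks onto many-core neuromorphic hardware of the
    SpiNNaker type. Provides event-driven synaptic row processing with
    fixed-point ring-buffer delay handling, deferred pair-based
    spike-timing-dependent plasticity (STDP) with a fixed-capacity
    postsynaptic history queue and flush events, clock-cycle cost models
    for neuron and synapse processors, and a partitioner that allocates
    neuron, synapse, and current-input virtual cores and audits real-time
    feasibility. Includes programmatic generators for Poisson-input,
    Vogels-Abbott, and modular-attractor benchmark networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
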