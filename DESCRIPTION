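Package: tripartite
Title: Simulation of GABA-Activated Astrocyte Modulation in Spiking Neuron
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Biophysical simulator of a tripartite-synapse network in which
    bath-applied GABA drives astrocytic IP3/calcium dynamics and
    calcium-triggered glutamate gliotransmission, which in turn comodulates
    excitatory presynaptic release (Tsodyks-Markram short-term plasticity
    with mGluR and GABA-B comodulation) and injects slow inward currents into
    postsynaptic conductance-based leaky integrate-and-fire neurons. Includes
    seeded spatial network construction (neurons, astrocyte lattice,
    synapse-to-astrocyte territories, gap-junction coupling), a fixed-step
    network engine with a compiled core, bath-GABA dose-series experiments,
    and analysis utilities for population rates, calcium oscillation
    statistics, release-probability series and EPSC/SIC event amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
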