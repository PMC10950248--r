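Package: vfsim
Title: Laminar Spiking-Network Simulation and Analysis of Visual-Flow
    Perturbation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds seeded synthetic laminar cortical columns (layers L1 to
    L6 with excitatory, Pvalb, Sst and Htr3a cell classes), simulates them
    as generalized leaky integrate-and-fire neurons with two after-spike
    currents (GLIF3) coupled by alpha-function synapses, and analyses the
    responses to visual-flow perturbations delivered through a simplified
    thalamic (LGN) front-end. Per-neuron input currents are decomposed by
    source (LGN, background, recurrent, after-spike), neurons are labeled
    as depolarized (dVf) or hyperpolarized (hVf) by visual flow relative
    to rheobase-scaled thresholds, and network structure and dynamics are
    summarised with effective synaptic weights, Ripley's K spatial
    statistics, direction and temporal-frequency sweeps, and a Welch-test
    statistics protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
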