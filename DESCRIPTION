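Package: dendropop
Title: Virtual Neuron Populations and Network Scaffolds for the Dentate Gyrus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for amplifying a small set of granule-cell dendritic
    reconstructions into large, biologically constrained virtual populations.
    Reads and writes SWC morphologies with shrinkage correction, extracts the
    basic morphometric parameters consumed by a Hillman-style stochastic
    dendritic growth algorithm and the emergent whole-cell parameters used for
    validation, fits and samples the four canonical parameter distributions
    (gamma, normal, uniform, constant), grows virtual dendritic trees, filters
    populations by emergent-parameter windows and resamples them to match
    target distributions, and lays out the structural scaffold of a full-scale
    dentate gyrus network model (cell counts, septotemporal placement, hilar
    injury, lamellar stimulation sets, and scale-dependent synaptic rules).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
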