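Package: mdfconn
Title: Morpho-Density Fields and Potential-Synapse Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates axonal and dendritic morpho-density fields (expected
    neurite length per unit volume around the soma, stored in cylindrical
    (r, z) coordinates) from ensembles of model-generated pyramidal-like
    neuron morphologies, and uses them to compute the expected number of
    potential synapses between displaced neuron pairs by three estimators:
    an overlap integral under uniformly-distributed segment orientations, an
    orientation-template estimator with seven principal directions, and a
    Gaussian-kernel estimator operating on raw segment inventories.  Includes
    a seeded stochastic neurite-outgrowth simulator with SWC input/output, a
    brute-force potential-synapse counting oracle, generation of random
    directed weighted neural networks from connectivity maps, and
    Latora-Marchiori global/local efficiency and cost measures for weighted
    directed graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
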