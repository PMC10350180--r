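Package: axonclass
Title: Statistical Classification of Neurons by Brain-Wide Axonal
    Projection Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies projection neuron types from whole-brain
    single-neuron reconstructions. Each neuron is represented as a vector
    of axonal point counts per brain region; a single-class null
    hypothesis is generated by margin-preserving swap randomization of
    the count matrix and tested with a one-tailed Levene variance test on
    pairwise arccosine distances, gating recursive average-linkage
    hierarchical splits. Identified classes are characterized by
    non-negative least-squares abundance deconvolution against regional
    anterograde tracing strengths, convex-hull soma topography with
    overlap volumes, and soma-to-target path-distance divergence and
    convergence statistics. Includes readers and writers for
    reconstruction JSON, SWC and count-matrix CSV, a synthetic-data
    generator for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    car,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
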