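Package: projcensus
Title: Cell-Type Projection Census Analysis for Mesoscale Connectomics
Version: 0.1.0
Authors@R: person("Projection", "Census Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative machinery for building cell-type wiring diagrams of
    a cortical area from multi-modal anatomical data: weighted connectivity
    matrices from anterograde and retrograde tracer experiments with
    blank-brain false-positive calibration; Spearman/complete-linkage
    clustering of projection patterns with layer-enrichment and contrast
    statistics; cortical sublayer delineation from binned soma depths;
    entropy-reduction recursive partitioning of barcoded single-neuron
    projections with laminar merging; XOR-distance discreteness testing
    against fixed-margin null matrices; and non-negative / bounded-variable
    least-squares deconvolution of bulk projection patterns into single-cell
    cluster proportions. Seeded synthetic-data generators with planted
    ground truth exercise every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
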