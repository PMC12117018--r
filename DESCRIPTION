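Package: clonetrackr
Title: Clonal Tracking and Transcriptional Plasticity Analysis for
    Barcoded Tumor Xenografts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative clonal lineage tracing of lentivirally
    barcoded patient-derived tumor xenografts. Turns barcode amplicon reads
    into collapsed per-library count tables, calibrates read counts to
    absolute clone sizes with spike-in controls, computes clone-initiating
    cell frequencies and in vivo doubling times, classifies clone growth
    speed with a Gaussian-mixture model selected by AIC, calls
    propagating/transient/emerging clone fates across serial passages, and
    links clones to transcriptional cell states through a metacell
    similarity-graph layer (root finding, transcriptional distances, gene
    modules, signature projections, pseudobulk differential expression).
    Includes stochastic simulators for clone growth and clone detection,
    and a synthetic-data module that generates every input the pipeline
    consumes together with ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
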