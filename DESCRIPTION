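Package: arcquant
Title: Responder Classification and Marker Coexpression Quantification for
    Arcuate Neuron Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline for slice electrophysiology and RNAscope
    imaging of hypothalamic feeding-circuit neurons. Implements firing-rate
    binning with baseline statistics and the 3-sigma responder criterion for
    bath-application protocols (with a membrane-potential fallback for silent
    neurons), z-score traces and population response summaries; segmentation
    of marker-positive cells from multi-channel fluorescence images (median
    filter, Triangle autothreshold, particle-area filter), punctum counting,
    dot-based positivity calls, per-cell intensity and coexpression tables
    with rank-sum subpopulation comparison; cluster-based subsetting of
    annotated single-cell count matrices with percent-expressing summaries;
    and seedable synthetic-data generators (dose-dependent point-process
    spike trains, disk-cell images with countable puncta, sparse labelled
    count matrices) that emit ground truth so every stage is testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    Matrix,
    methods,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
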