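Package: preplateR
Title: Integrative Temporal Transcriptome and Chromatin-State Analysis of
    Preplate and Cajal-Retzius Neuron Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating FACS-sorted bulk
    RNA-seq, histone-mark ChIP-seq peaks and single-cell RNA-seq across
    early cortical neurogenesis. Implements stage-wise enrichment and
    marker-gene filter cascades on FPKM tables, trinarized temporal
    trajectory classification over a 27-class space, TSS/distal peak
    assignment with mono/bivalent chromatin-state calls and histone-by-
    expression contingency tests, and single-cell QC, clustering and
    pseudotime-state grouping, together with a synthetic-data generator
    that plants ground-truth labels for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
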