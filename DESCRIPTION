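Package: endonet
Title: Factorial Transcription-Factor Interactions and Dynamic Coexpression
    Networks in Cereal Endosperm Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial mutant transcriptomics of
    developing cereal endosperm. Provides a synthetic multi-omic data
    generator emulating an 8-genotype x 3-timepoint factorial design with
    planted coexpression modules and transcription-factor binding peaks;
    negative-binomial GLM differential expression with median-of-ratios
    normalization, method-of-moments dispersion shrinkage and Wald tests;
    signed weighted coexpression networks with topological overlap, module
    eigengenes, module merging and hub calling; factorial interaction testing
    and module-level epistasis classification; peak-to-gene target assignment
    within TSS windows, consensus-motif scanning, differential chromatin
    accessibility and peak-location categories; and cross-timepoint module
    flow tracing with hierarchical TF-hub-member network assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    jsonlite,
    MASS,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    withr
Config/testthat/edition: 3
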