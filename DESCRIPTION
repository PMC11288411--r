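Package: trforge
Title: Transcriptional Regulator Activity and Gene Regulatory Networks from
    Single-Cell and Spatial Multiomics
Version: 0.1.0
Authors@R: person("trforge", "developers", email = "trforge@example.org",
    role = c("aut", "cre"))
Description: Infers transcriptional-regulator (TR) activity scores and
    TR-centred gene regulatory networks from single-cell RNA-seq, paired
    multiome and spatial transcriptomics data.  Cells are aggregated into
    SuperCells by two-level Leiden clustering; TR cistromes are scored
    against genes with an exponential-decay regulatory-potential model;
    in-silico deletion of TR binding sites from reconstructed or paired
    chromatin landscapes yields per-TR significance via one-sided Wilcoxon
    tests combined by the Cauchy combination test; an expression-corrected
    activity score integrates TR and target-gene expression.  Includes a
    spatial graph-attention auto-encoder, an exact optimal-transport
    Wasserstein statistic for ligand-receptor analysis, and a synthetic-data
    generator with planted regulons for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
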