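Package: regcompare
Title: Cross-Species Comparison of Histone-Mark-Defined Regulatory Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing tissue regulatory landscapes between two
    species from histone-mark ChIP-seq peaks.
    Classifies reproducible H3K4me3/H3K27ac peaks into putative promoters
    and enhancers by mark co-occupancy and TSS distance, maps elements
    between genomes through UCSC alignment chains with a reciprocal
    nearest-gene filter to call conserved versus species-specific activity,
    integrates TPM/CPM expression thresholds, soft-clusters z-scaled
    temporal expression profiles with fuzzy c-means and the
    Calinski-Harabasz criterion, and tests cluster, gene-set and motif
    enrichment with exact tests and multiple-testing control. A
    synthetic-data generator plants ground-truth elements, orthology-
    consistent chain files and negative-binomial count matrices so the
    whole pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    vegan,
    edgeR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, FunctionalGenomics, ChIPSeq, GeneExpression,
    Clustering, MotifAnnotation
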