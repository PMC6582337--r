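Package: hotRegions
Title: Calling and Characterizing High-Occupancy Target (HOT) Regions
    from ChIP-seq Peak Collections
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls high-occupancy target (HOT) regions from large
    collections of ChIP-seq peak sets by pooled peak-summit density in
    sliding windows with local-maximum suppression and percentile
    thresholding. Characterizes the called regions with k-mer, CpG
    observed/expected, GC-content and GC-skew sequence features, trains
    elastic-net discriminators of HOT versus lower-occupancy control
    regions, quantifies IP-versus-control log2 enrichment (knockout
    ChIP-seq, DRIP-seq, G4 ChIP-seq style designs) with binned metaregion
    profile matrices, and summarizes whole-genome bisulfite methylation
    medians and interquartile ranges across cell types. Ships a fully
    seeded synthetic-data generator (genomes with planted CpG-rich loci,
    pseudo peak experiments, reads with planted fold changes, methylation
    tables) so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: ChIPSeq, Epigenetics, Sequencing, Classification, Software
RoxygenNote: 7.3.3
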