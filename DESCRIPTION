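Package: medipdmr
Title: MeDIP-Chip Differential Methylation Regions and Epigenetic Control
    Region Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-colour MeDIP-Chip promoter tiling
    arrays: MA conversion, GC-grouped within-array loess normalization,
    A-quantile normalization across arrays, 600 bp windowed median
    smoothing, empirical probe Z-scores with all-pairs intersection of
    comparative hybridizations, clustering of significant probes into
    differential DNA methylation regions (DMRs) with intensity and CpG
    density filters, DMR genomic-feature characterization (CpG density
    histograms, IUPAC/PWM motif incidence against a random promoter
    background, cross-set overlap), a three-criterion differential
    expression selection rule with a two-factor treatment + batch test,
    and a 2 Mb sliding-window detector of chromosomal clusters of
    differentially expressed genes (epigenetic control regions, ECRs).
    Includes a synthetic-data generator emulating NimbleGen promoter-array
    geometry with planted DMRs, DE genes, gene clusters and motif sites,
    against which parameter recovery is scored.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    limma,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
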