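Package: mpramap
Title: Design and Inference for Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for massively parallel reporter assay
    (MPRA) studies of cis-regulatory elements and variant effects: oligo
    library design (strand tiling, per-base saturation mutagenesis, known
    SNV/InDel variants with parity-aware centering, GC-matched scrambled
    controls), barcode-to-element association with multi-mapping removal
    and CIGAR length filtering, RNA/DNA activity quantification against a
    robust median/MAD empirical null of scrambled controls, joining of
    significant elements into candidate cis-regulatory elements (CREs)
    with ENCODE cCRE annotation, allele-effect log fold-change estimation
    with gain/loss calls and cross-cell-type sharing classification, and a
    fully specified synthetic-data generator (log-normal DNA abundance,
    negative-binomial RNA counts) so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
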