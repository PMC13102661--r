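Package: scMirEdit
Title: miRNA Mutation and Editing Analysis for Single-Cell Small RNA Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes miRNA mutation/editing (M/E) sites in
    single-cell small RNA sequencing profiles. Reads are quality-filtered,
    collapsed and aligned to pre-miRNA hairpins with an exact aligner that
    separates the templated read body from short non-templated 3' tails;
    multi-mapping reads receive cross-mapping weights by iterative
    expression-proportional reallocation. Per-cell editing sites are called
    from weighted pileups under a binomial sequencing-error model with
    Benjamini-Hochberg correction and classified into nine types (A-to-I,
    C-to-U, 3'-A, 3'-U, 3'-Other, 5'-editing, Other, SNP, Pseudo). Cohort
    analyses include prevalence filtering, PCA, hierarchical biclustering,
    cell-type-specific site detection via indicator correlation, editing-level
    variance tiers, Mann-Whitney differential editing, and correlation of 3'
    addition levels with terminal nucleotidyltransferase (TENT) expression.
    A seeded synthetic-cohort generator produces reference hairpins, per-cell
    FASTQ files and ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, Sequencing, RNAEditing, Software
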