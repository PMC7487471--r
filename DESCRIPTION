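Package: selalign
Title: Decoy-Aware Selective Alignment and Quantification for RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements decoy-aware selective alignment for RNA-seq transcript
    quantification: a unitig-based k-mer index over the transcriptome plus decoy
    sequences, five-phase read mapping (uni-MEM collection, hit collation and
    filtering, anchor chaining, paired-end merging, score-only extension
    alignment), a decoy decision rule that discards fragments better explained
    by unannotated genomic sequence, decoy-sequence extraction from an
    exon-masked genome via minimizer/minhash segment mapping, curation of oracle
    alignment sets from two aligners by MD-tag matched-base scoring, and
    equivalence-class EM abundance estimation with range-factorized classes.
    A synthetic-data generator (annotated genomes, variant transcriptomes,
    planted unannotated loci, paired-end reads with truth tables) makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    Matrix,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    S4Vectors,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
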