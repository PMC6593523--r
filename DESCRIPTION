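Package: regulonScout
Title: Transcription-Factor Regulon Inference from Bacterial Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor regulons in bacterial genomes from a
    two-condition RNA-seq count matrix and a genome annotation. Provides
    negative-binomial differential expression with fold-change/FDR selection,
    promoter-window extraction (500 bp upstream plus 50 bp downstream of start
    codons), seeded ZOOPS expectation-maximisation motif discovery with
    palindrome and simple-repeat candidacy filtering, position-weight-matrix
    scanning with exact score p-values and a dual-scheme consensus rule,
    operon-level site propagation, ddCq qPCR fold changes, and
    conservation-rank substitution profiles. Includes a synthetic-data
    generator (genomes with planted binding sites, negative-binomial counts,
    Cq tables, protein alignments) so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
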