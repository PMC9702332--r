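Package: miredit
Title: Identification of miRNA Mutation and Editing Sites from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying miRNA mutation and editing (M/E)
    sites from small RNA sequencing profiles: read quality screening and
    adapter trimming, mismatch-tolerant alignment of collapsed reads to
    pre-miRNA hairpins with 3'-tail decomposition, genome alignment with
    cross-mapping correction of multi-mapped reads, per-sample binomial
    significance testing of candidate sites against the Phred-implied
    sequencing-error rate, nine-category site classification (A-to-I,
    C-to-U, 3'-A, 3'-U, 3'-Other, 5'-editing, Other, SNP, Pseudo), cohort
    aggregation with sample-fraction retention and SNP reclassification,
    differential editing between cohorts (Mann-Whitney U with
    Benjamini-Hochberg correction), and multivariate sample analysis
    (quantile normalization, PCA, correlation-distance Ward clustering).
    Includes a small-RNA read simulator with machine-readable ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    limma,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
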