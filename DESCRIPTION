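Package: bsmeth
Title: Bisulfite Sequencing Alignment, Methylation Calling and
    Differential Methylation Analysis
Version: 0.1.0
Authors@R:
    person("bsmeth", "developers", email = "bsmeth@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for bisulfite sequencing (BS-seq) data:
    indel-sensitive read alignment on three-letter converted genomes with
    long-seed candidate search and affine-gap extension, per-cytosine
    methylation calling with reverse-strand SNP correction, region and
    meta-gene methylation summaries, and detection of differentially
    methylated cytosines and regions by Fisher's exact test (no replicates)
    or a beta-binomial likelihood-ratio test (with replicates).  Includes a
    read simulator with full ground truth and an evaluator implementing
    position-, strand- and indel-based correctness criteria, so the whole
    pipeline is testable on synthetic data.  Supports in-silico MspI
    digestion for reduced representation bisulfite sequencing (RRBS).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
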