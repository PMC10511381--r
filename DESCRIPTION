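Package: ccrpipe
Title: Breakpoint Junction Analysis for Complex Chromosomal Rearrangements
Version: 0.1.0
Authors@R:
    person("ccrpipe", "developers", email = "ccrpipe@example.org",
           role = c("aut", "cre"))
Description: Nucleotide-resolution analysis of breakpoint junctions from
    constitutional complex chromosomal rearrangements (CCRs) such as
    chromothripsis-like three-way translocations. Calls junction signatures
    (blunt joins, microhomology, microinsertions and templated insertions),
    reconstructs derivative chromosome structures from a junction set with
    copy-number accounting, and tests for enrichment of breakpoints in
    chromatin-accessibility peak sets (ATAC-seq, ChIP-seq, MNase-seq) by
    windowed Poisson regression with Wald confidence intervals. Includes
    parent-of-origin assignment from trio genotypes near junctions, a fully
    ground-truthed synthetic-data generator so every stage is testable
    without external downloads, and a command-line pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
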