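Package: pairwalk
Title: Contact Calling, Multimapping Trimming and Breakpoint Detection for
    Multiomic Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes locally aligned paired-end reads from multiomic
    single-cell Hi-C assays (e.g. LiMCA, snm3C-seq) into chromatin contacts.
    Builds an in-silico restriction map of the reference genome, derives
    read-coordinate spans of soft-clipped chimeric alignments from their
    CIGAR strings, filters alignments by mapping quality, trims multimapped
    read bases shared by adjacent soft-clipped alignments (the sticky-end
    proximity-ligation artifact), calls contacts under a two-locus ("mask")
    and a multi-locus ("all") policy, annotates contacts with restriction
    cut-site proximity to flag likely structural-variant junctions, calls
    1 bp-resolution breakpoints from adjacent soft-clipped alignments, and
    reports quality-control metrics. Outputs 4DN PAIRS, SAM/BAM and BEDPE.
    Includes a ground-truth simulator of ligation products for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    GenomicAlignments,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
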