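Package: cryptsplice
Title: Discovery of Splice-Site-Creating Mutations from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects non-canonical splice junctions activated by somatic
    non-coding mutations from spliced RNA-Seq alignments. Junctions within a
    configurable window of each mutation are extracted from CIGAR skip
    operations, passed through known-junction, coverage/junction-allele-
    fraction and case/control filters, scored with a position log-odds
    splice-site model (donor 9-mers, acceptor 23-mers), and classified into a
    seven-way event taxonomy (new exon, exon extension/shrinkage/splitting,
    fusion, new transcript, complex). Includes the accompanying statistical
    toolkit (binomial power/required depth, Poisson artifact thresholds,
    long-intron bias model, Tukey expression outliers, Fisher enrichment) and
    a read-level simulator for sensitivity benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    parallel,
    stats,
    utils,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
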