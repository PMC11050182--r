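Package: g4landscape
Title: Genome-Wide G-Quadruplex and Microsatellite Landscape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects potential G-quadruplex forming sequences with a run-based
    guanine-skew score evaluated in sliding windows, detects microsatellites
    (simple sequence repeats) with MISA-style thresholds, and summarises their
    joint landscape over genomic feature regions (exon, CDS, intron, UTRs,
    gene, intergenic, promoter windows, TSS-centred windows) under double-,
    template- and coding-strand contexts. Includes promoter G4-count gene
    classification, differential-expression gene-set density contrasts,
    hypergeometric term over-representation with Benjamini-Hochberg
    correction, a synthetic-genome simulator with planted ground truth for
    end-to-end validation, and a one-call pipeline producing BED, bedGraph and
    TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
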