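Package: bessurvey
Title: BAC-End Sequence Survey, Annotation and Comparative Mapping
Version: 0.1.0
Authors@R:
    person("Wei", "Tan", email = "wtan.genomics@example.org",
           role = c("aut", "cre"))
Description: Tools for genome surveys built on BAC-end sequences (BES):
    quality and vector trimming, redundancy filtering and survey
    statistics; repeat-library merging, repeat masking with divergence
    profiles and transposon-protein scanning; perfect-microsatellite
    detection and motif census; seed-and-extend anchoring of BES onto a
    reference genome with BLAST-style tabular interchange; mate-pair
    classification, microsynteny construction and typing against gene
    annotation; and per-chromosome physical-coverage reporting. A
    simulator generates reference genomes, diverged sample genomes and
    clone-end reads with ground truth so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    tibble,
    dplyr,
    withr,
    rtracklayer,
    ggplot2,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
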