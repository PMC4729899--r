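Package: okseqr
Title: Replication Fork Directionality Analysis of OK-Seq Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse genome-wide Okazaki fragment sequencing (OK-seq)
    data: computation of replication fork directionality (RFD) profiles from
    strand-specific read counts, four-state hidden Markov model segmentation of
    RFD profiles into initiation (ascending), termination (descending) and
    unidirectional (flat) zones with per-zone efficiencies, S50 replication
    timing from multi-fraction Repli-seq, nucleotide compositional skew and
    G-quadruplex motif scanning, gene-context classification of initiation
    zones with a timing-stratified randomization null, and Hi-C directionality
    index. Includes a stochastic simulator of the underlying replication
    program (broad initiation zones firing at most once per cell, background
    origins with time-increasing firing rate, constant fork speed) that
    produces synthetic OK-seq and Repli-seq data with known ground truth for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    GenomicRanges
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, Epigenetics, Coverage, HiddenMarkovModel
RoxygenNote: 7.3.3
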