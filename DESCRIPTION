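Package: chimfuse
Title: Discovery and Validation of Chimeric mRNAs from Transcript
    Alignments and RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer putative chimeric (trans-spliced) mRNAs from
    split alignments of transcripts to a genome and to validate them with
    independent evidence. Covers identity/length/junction-gap filtering of
    alignments, fusion-geometry classification, verification of the fusion
    point on an artificially fused genomic reference (junction precision,
    GT-AG splice signals, reading-frame integrity), EST support scoring,
    junction-read quantification from single-end RNA-seq with overhang
    windows, expression-variability statistics (coefficient of variation,
    exact rank-sum tests), and shared-motif analysis of parental genomic
    regions against a position-frequency-matrix library. A seeded
    synthetic-data generator with a known truth table exercises every
    stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
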