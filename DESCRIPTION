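Package: lpdissect
Title: Dissection of Enhancer Activity from Landing-Pad Sort-Seq Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recombinase-mediated enhancer dissection screens read out
    by sort-seq / HCR-FlowFISH. Implements conservation-guided transversion
    design of transcription-factor motif mutant libraries with tiling deletions
    and mix-and-match double mutants, barcode quantification from sorted-bin
    FASTQ files with quality masking and background-coverage filtering,
    weighted-average activity scoring against bin fluorescence summaries,
    calibration of scores to relative expression with log-additive
    (multiplicative) epistasis testing and facilitator power-law buffering fits,
    delta-delta-Ct and ChIP percent-input quantification, and strand-aware
    nascent-transcription summaries (pausing index, reciprocal-overlap consensus
    peaks, median-of-ratios scaling). A synthetic sort-seq generator with known
    ground truth exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
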