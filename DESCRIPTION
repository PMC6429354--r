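Package: chronoswitch
Title: Time-Course Isoform Switch Detection and Consequence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects pairwise isoform expression switches in transcript-level
    TPM time series, scores them with the switch-magnitude statistic S2 and
    companion metrics (switch probability, paired t p-value, isoform
    correlation), locates switch time peaks (STPs) in 3-hour bins, classifies
    the predicted functional consequences of switching isoform pairs (coding
    potential, ORF length and similarity, nonsense-mediated decay, intron
    retention, protein-domain gain and loss, alternative splicing events) and
    performs hypergeometric over-representation analysis of switching-gene
    sets. Ships a synthetic circadian time-course generator with planted
    switches and consequence truth so every pipeline stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    IRanges,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
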