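Package: hashsv
Title: Hash-Based Amplicon Sequence Variant Inference with a
    Depth-Calibrated Error Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fast, conservative de novo inference of 16S rRNA amplicon
    sequence variants. Unique reads are dereplicated by hash-map counting
    with per-sample singleton removal, then greedily grouped into clusters
    of an abundant parent sequence and its one-mismatch children. A single
    per-base substitution error rate is estimated by fitting a one-parameter
    Poisson presence/absence model to the fraction of possible one-mismatch
    children observed per parent. True variants are separated from
    sequencing error by a one-sided normal test on log10 child abundance
    whose background mean and standard deviation are calibrated by LOESS
    regression against log10 parent depth, with Benjamini-Hochberg control
    of the false-discovery rate. A polymerase-error read simulator with
    known ground truth is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
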