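Package: epicontext
Title: Context-Conditioned Prediction of Epigenomic Signals from Sequence and Transcription-Factor Expression
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scale-configurable transformer model that predicts binned
    epigenomic signals (DNase, CTCF and six histone marks) from genomic DNA
    sequence conditioned on a cellular context described by transcription-factor
    expression. Includes the preprocessing arithmetic (sequencing-depth
    normalization, log1p, binarization, quantile normalization), PWM motif
    scanning, a multi-head self-attention encoder with extractable attention
    maps, masked multi-task training with an optional chromatin-contact
    attention-guidance loss, gradient-based TF importance scores, log-ratio
    variant-effect scores, attention-based element-gene scoring, evaluation
    metrics, and a synthetic-data generator with planted, recoverable
    regulatory structure. All gradients are computed by a small built-in
    reverse-mode automatic-differentiation tape, so the package has no
    deep-learning framework dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
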