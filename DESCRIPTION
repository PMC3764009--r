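Package: motifHMM
Title: Hidden Markov Models of Transcription Factor Binding Sites with
    Dinucleotide Dependencies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds, trains and applies transcription factor flexible
    models (TFFMs): hidden Markov models of transcription factor binding
    sites whose emissions depend on the previously observed nucleotide,
    capturing dinucleotide dependencies and variable motif lengths.
    Provides Baum-Welch training, forward-backward posterior scanning on
    both strands, probability-of-occupancy scores, summary and dense
    sequence logos, a PWM log-odds baseline, a cross-validated ROC/AUC
    benchmarking protocol with GC-matched and Markov-chain backgrounds,
    and a synthetic peak-sequence generator with known ground truth.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
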