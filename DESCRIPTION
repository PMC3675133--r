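Package: thetahippo
Title: Theta-Phase Error-Driven Learning in a Hippocampal Network Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rate-coded neural network model of the hippocampal circuit
    (entorhinal cortex, dentate gyrus, CA3, CA1) in which projection strengths
    are gated across three phases of the theta cycle. The phase contrast
    between an attempted recall and a target encoding yields two error-driven
    learning signals, one for the monosynaptic EC-CA1 pathway and one for the
    CA3-CA1 Schaffer collaterals, alongside conditional-PCA Hebbian learning
    elsewhere. Includes a synthetic generator of slot-structured binary input
    patterns with a minimum pairwise Hamming distance, k-winners-take-all
    inhibition, contrastive Hebbian plasticity, pattern-completion recall from
    partial cues, Name Error scoring, capacity sweep experiments comparing
    error-driven against purely Hebbian learning, and bootstrap significance
    tests of the comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
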