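Package: cnvpower
Title: Power of Copy-Number Association Tests under Calling Errors and
    Intensity Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the errors made by hidden-Markov-model copy-number
    variation (CNV) calling algorithms and their consequences for
    quantitative-trait association testing. Provides closed-form moments of
    the call-error term at Hardy-Weinberg CNV loci, a Gaussian noise model
    for log R ratio (LRR) intensities, Monte-Carlo and analytic
    (noncentral-F) power calculations for regression tests on error-prone
    calls versus raw intensities, a synthetic probe-grid LRR cohort
    generator with PennCNV-style signal-file input/output, and a
    five-state Viterbi segmenter with recovery-rate curves by CNV size
    and type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
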