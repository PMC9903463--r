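Package: endoner
Title: Named Entity Recognition for Colonoscopy Reports with Bi-LSTM-CRF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for extracting procedural information and colonoscopic
    findings from free-text colonoscopy reports by named entity recognition.
    Implements a 17-label annotation schema (sedation, medication, bowel
    preparation, lesions, anatomical locations, sizes, negation and more),
    IOB2 span encoding, CBOW word-embedding pretraining on unlabeled report
    corpora, a bidirectional LSTM sequence encoder with a linear-chain
    conditional random field output layer (forward-algorithm likelihood,
    constrained Viterbi decoding), partial-match entity-level evaluation with
    fivefold cross-validation, and a synthetic colonoscopy-report generator
    for benchmarking when institutional data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
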