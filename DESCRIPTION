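Package: nerlstm
Title: Clinical Entity Recognition with Bidirectional LSTM-CRF Sequence Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognizes typed entity mentions (clinical concepts, protected
    health information) in free text with a bidirectional peephole-LSTM
    encoder and a linear-chain conditional random field inference layer.
    Provides rule-based sentence splitting and character-class tokenization,
    BIOES tag encoding and decoding with deterministic repair, token-level
    embeddings loadable from word2vec text format, character-level word
    representations from a character bi-LSTM or a character CNN, exact
    Viterbi decoding and forward-algorithm likelihood in log space,
    per-sentence stochastic gradient descent training with global-norm
    gradient clipping, micro-averaged evaluation under exact, inexact, span,
    type and token matching criteria, and a seeded generator of synthetic
    clinical-style annotated corpora so the full pipeline is testable
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
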