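# shared fixture builders (everything is generated in code; no data files)

# tokens tibble for a single sentence laid out with single spaces
toy_tokens <- function(words, offset = 0L) {
  ends <- cumsum(nchar(words)) + seq_along(words) - 1L
  starts <- ends - nchar(words)
  tibble::tibble(token = words, start = starts + offset, end = ends + offset)
}

toy_mention <- function(type, start, end, doc_id = NULL) {
  m <- tibble::tibble(type = type, start = as.integer(start),
                      end = as.integer(end))
  if (!is.null(doc_id)) m <- tibble::tibble(doc_id = doc_id, m)
  m
}

# zeroed LSTM parameters of a given shape
zero_lstm <- function(input_dim, hidden) {
  p <- lstm_params(input_dim, hidden, seed = 1)
  p$Wx[] <- 0; p$Wh[] <- 0; p$p_i[] <- 0; p$p_f[] <- 0; p$p_o[] <- 0; p$b[] <- 0
  p
}

# random CRF with nonzero weights
random_crf <- function(labels, width, parameterization = "pairvec", sd = 0.5) {
  crf <- crf_params(labels, width, parameterization = parameterization)
  if (parameterization == "pairvec") {
    crf$theta[] <- stats::rnorm(length(crf$theta), sd = sd)
  } else {
    crf$W[] <- stats::rnorm(length(crf$W), sd = sd)
    crf$A[] <- stats::rnorm(length(crf$A), sd = sd)
  }
  crf
}

# independent enumeration oracle: score of every label sequence, scored by
# explicit per-position dot products (no forward recursion involved)
enumerate_scores <- function(crf, context) {
  k <- length(crf$labels); n <- nrow(context)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  scores <- apply(grid, 1, function(ys) {
    prev <- c(k + 1L, ys[-n])
    s <- 0
    for (t in seq_len(n)) {
      if (crf$parameterization == "pairvec") {
        s <- s + sum(crf$theta[, prev[t], ys[t]] * context[t, ])
      } else {
        s <- s + sum(crf$W[ys[t], ] * context[t, ]) + crf$A[prev[t], ys[t]]
      }
    }
    s
  })
  list(grid = grid, scores = scores)
}

# small trainable corpus (tagged tokens) built from the generator
toy_corpus <- function(n_documents = 6, seed = 5, oov_rate = 0,
                       density = 1.0, sentences = c(3L, 5L)) {
  generate_corpus(corpus_spec(n_documents = n_documents,
                              sentences_per_doc = sentences,
                              entity_density = density,
                              oov_rate = oov_rate, seed = seed))
}

small_config <- function(...) {
  defaults <- list(token_dim = 8, char_dim = 6, char_lstm_size = 6,
                   char_cnn_filter_number = 6, token_lstm_size = 8,
                   dropout = 0, learning_rate = 0.05, epochs = 5, seed = 42)
  do.call(ner_config, utils::modifyList(defaults, list(...)))
}
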