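# independent scalar transcription of the peephole recurrences, written
# directly from the gate formulas with no vector operations
scalar_lstm_step <- function(p, x, h_prev, c_prev) {
  H <- p$hidden; d <- p$input_dim
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cc <- numeric(H)
  for (j in seq_len(H)) {
    zi <- 0; zf <- 0; zc <- 0; zo <- 0
    for (m in seq_len(d)) {
      zi <- zi + p$Wx[j, m] * x[m]
      zf <- zf + p$Wx[H + j, m] * x[m]
      zc <- zc + p$Wx[2 * H + j, m] * x[m]
      zo <- zo + p$Wx[3 * H + j, m] * x[m]
    }
    for (m in seq_len(H)) {
      zi <- zi + p$Wh[j, m] * h_prev[m]
      zf <- zf + p$Wh[H + j, m] * h_prev[m]
      zc <- zc + p$Wh[2 * H + j, m] * h_prev[m]
      zo <- zo + p$Wh[3 * H + j, m] * h_prev[m]
    }
    i_t <- sig(zi + p$p_i[j] * c_prev[j] + p$b[j])
    f_t <- sig(zf + p$p_f[j] * c_prev[j] + p$b[H + j])
    cc[j] <- f_t * c_prev[j] + i_t * tanh(zc + p$b[2 * H + j])
    o_t <- sig(zo + p$p_o[j] * cc[j] + p$b[3 * H + j])
    h[j] <- o_t * tanh(cc[j])
  }
  list(h = h, c = cc)
}

test_that("zero parameters and zero state give exactly zero output", {
  p <- zero_lstm(3, 2)
  out <- lstm_step(p, c(5, -2, 7), list(h = c(0, 0), c = c(0, 0)))
  expect_identical(out$h, c(0, 0))
  expect_identical(out$c, c(0, 0))
})

test_that("vectorized step matches the scalar transcription on random shapes", {
  set.seed(101)
  for (rep in 1:25) {
    d <- sample(1:5, 1); H <- sample(1:5, 1)
    p <- lstm_params(d, H, seed = rep)
    x <- rnorm(d); h0 <- tanh(rnorm(H)); c0 <- rnorm(H)
    fast <- lstm_step(p, x, list(h = h0, c = c0))
    slow <- scalar_lstm_step(p, x, h0, c0)
    expect_equal(fast$h, slow$h, tolerance = 1e-12)
    expect_equal(fast$c, slow$c, tolerance = 1e-12)
  }
})

test_that("a saturated forget gate carries the cell state through", {
  p <- zero_lstm(2, 3)
  p$b[4:6] <- 20  # forget-gate bias block
  v <- c(0.3, -1.2, 2.5)
  out <- lstm_step(p, c(0, 0), list(h = c(0, 0, 0), c = v))
  expect_equal(out$c, v, tolerance = 1e-6)
})

test_that("hidden entries stay in (-1, 1) and states stay finite", {
  set.seed(55)
  p <- lstm_params(4, 6, seed = 9)
  st <- list(h = rep(0, 6), c = rep(0, 6))
  for (t in 1:1000) {
    st <- lstm_step(p, rnorm(4, sd = 2), st)
    expect_true(all(abs(st$h) < 1))
    expect_true(all(is.finite(st$c)))
  }
})

test_that("sequence forward pass equals repeated single steps", {
  set.seed(12)
  p <- lstm_params(3, 4, seed = 3)
  X <- matrix(rnorm(15), 5, 3)
  fw <- nerlstm:::lstm_forward(p, X)
  st <- list(h = rep(0, 4), c = rep(0, 4))
  for (t in 1:5) {
    st <- lstm_step(p, X[t, ], st)
    expect_equal(fw$H[t, ], st$h, tolerance = 1e-12)
    expect_equal(fw$C[t, ], st$c, tolerance = 1e-12)
  }
})

test_that("bi-LSTM concatenates forward and backward states", {
  set.seed(4)
  pf <- lstm_params(3, 2, seed = 1); pb <- lstm_params(3, 2, seed = 2)
  x <- matrix(rnorm(3), 1, 3)
  ctx <- run_bilstm(pf, pb, x)$context
  sf <- lstm_step(pf, x[1, ], list(h = c(0, 0), c = c(0, 0)))
  sb <- lstm_step(pb, x[1, ], list(h = c(0, 0), c = c(0, 0)))
  expect_equal(drop(ctx), c(sf$h, sb$h), tolerance = 1e-12)
  expect_equal(ncol(ctx), 4L)  # exactly twice the directional size

  expect_error(run_bilstm(pf, pb, matrix(0, 0, 3)),
               class = "nerlstm_value_error")
})

test_that("reversing inputs and swapping directions reverses the context", {
  set.seed(40)
  pf <- lstm_params(3, 4, seed = 5); pb <- lstm_params(3, 4, seed = 6)
  X <- matrix(rnorm(18), 6, 3)
  a <- run_bilstm(pf, pb, X)$context
  b <- run_bilstm(pb, pf, X[6:1, , drop = FALSE])$context
  swapped <- cbind(b[6:1, 5:8], b[6:1, 1:4])
  expect_equal(a, swapped, tolerance = 1e-12)

  # palindromic input with shared parameters is symmetric under the same map
  Xp <- rbind(X[1:3, ], X[3:1, ])
  cp <- run_bilstm(pf, pf, Xp)$context
  expect_equal(cp, cbind(cp[6:1, 5:8], cp[6:1, 1:4]), tolerance = 1e-12)
})

test_that("char bi-LSTM representation equals the sequence-level encoder", {
  ct <- init_random_table(letters, 3, seed = 2)
  pf <- lstm_params(3, 4, seed = 7); pb <- lstm_params(3, 4, seed = 8)
  v <- char_repr_bilstm(ct, pf, pb, "pain")
  E <- lookup_sequence(ct, strsplit("pain", "")[[1]], lowercase = FALSE)
  ctx <- run_bilstm(pf, pb, E)$context
  expect_equal(v, c(ctx[4, 1:4], ctx[1, 5:8]), tolerance = 1e-12)
  expect_length(v, 8L)

  # one-character word: both directions see the single character
  v1 <- char_repr_bilstm(ct, pf, pb, "a")
  s <- lstm_step(pf, drop(lookup_sequence(ct, "a", lowercase = FALSE)),
                 list(h = rep(0, 4), c = rep(0, 4)))
  expect_equal(v1[1:4], s$h, tolerance = 1e-12)

  z <- char_repr_bilstm(ct, zero_lstm(3, 4), zero_lstm(3, 4), "pain")
  expect_identical(z, rep(0, 8))
  expect_error(char_repr_bilstm(ct, pf, pb, ""), class = "nerlstm_value_error")
})

test_that("char CNN matches a position-by-position loop oracle", {
  set.seed(63)
  ct <- init_random_table(letters, 3, seed = 4)
  cnn <- char_cnn_params(3, k = 3, n_filters = 5, seed = 6)
  cnn$b <- rnorm(5) * 0.1
  word <- "pain"
  v <- char_repr_cnn(ct, cnn, word)

  # loop oracle: explicit padding, window extraction, dot product, max
  E <- lookup_sequence(ct, strsplit(word, "")[[1]], lowercase = FALSE)
  P <- rbind(rep(0, 3), E, rep(0, 3))
  oracle <- vapply(1:5, function(j) {
    resp <- vapply(seq_len(nrow(E)), function(q) {
      sum(matrix(cnn$W[j, ], 3, 3) * P[q:(q + 2), ]) + cnn$b[j]
    }, numeric(1))
    max(resp)
  }, numeric(1))
  expect_equal(v, oracle, tolerance = 1e-12)
})

test_that("char CNN edge cases: zero filters, single-window word", {
  ct <- init_random_table(letters, 3, seed = 4)
  cnn0 <- char_cnn_params(3, k = 3, n_filters = 5, seed = 1)
  cnn0$W[] <- 0
  expect_identical(char_repr_cnn(ct, cnn0, "pain"), rep(0, 5))

  # length-1 word with k = 3: exactly one window [pad, c, pad]
  cnn <- char_cnn_params(3, k = 3, n_filters = 2, seed = 3)
  v <- char_repr_cnn(ct, cnn, "a")
  emb <- drop(lookup_sequence(ct, "a", lowercase = FALSE))
  manual <- vapply(1:2, function(j) {
    kern <- matrix(cnn$W[j, ], 3, 3)  # rows = window positions
    sum(kern[2, ] * emb) + cnn$b[j]
  }, numeric(1))
  expect_equal(v, manual, tolerance = 1e-12)
  expect_error(char_cnn_params(3, k = 4, n_filters = 2, seed = 1),
               class = "nerlstm_value_error")
  expect_error(char_repr_cnn(ct, cnn, ""), class = "nerlstm_value_error")
})

test_that("word-input widths follow the mode arithmetic", {
  cc <- toy_corpus(n_documents = 2, seed = 21)
  corpus <- corpus_tokens(cc$train)
  types <- sort(unique(sub("^[BIES]-", "", corpus$tag[corpus$tag != "O"])))
  vocab <- unique(corpus$token)
  alpha <- sort(unique(strsplit(paste(vocab, collapse = ""), "")[[1]]))
  widths <- c(token = 50, `char-lstm` = 100, `char-cnn` = 75, both = 125)
  for (mode in names(widths)) {
    m <- ner_model(types, vocab, alpha, mode = mode, config = ner_config())
    X <- build_word_inputs(m, c("chest", "pain"))
    expect_equal(ncol(X), unname(widths[mode]))
    expect_equal(nrow(X), 2L)
  }
  expect_error(ner_model(types, vocab, alpha, mode = "bogus"),
               class = "nerlstm_value_error")
})

test_that("inverted dropout is unbiased and inert outside training", {
  M <- matrix(1, 200, 500)
  expect_identical(apply_dropout(M, 0), M)
  expect_identical(apply_dropout(M, 0.7, training = FALSE), M)
  set.seed(2)
  D <- apply_dropout(M, 0.5)
  expect_lt(abs(mean(D) - 1), 0.02)
  expect_true(all(D %in% c(0, 2)))
  expect_error(apply_dropout(M, 1), class = "nerlstm_value_error")
  expect_error(apply_dropout(M, -0.1), class = "nerlstm_value_error")
  # seeded masks are reproducible
  expect_identical(apply_dropout(M, 0.5, seed = 9), apply_dropout(M, 0.5, seed = 9))
})
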