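test_that("sequence scores are transition-vector dot products summed over t", {
  labels <- c("A", "B")
  crf <- crf_params(labels, 2)
  ctx <- matrix(c(1, 1), 1, 2)
  expect_equal(sequence_score(crf, ctx, "A"), 0)  # all-zero weights

  crf$theta[, 3, 1] <- c(1, 1)   # START -> A scores 2 on h = (1,1)
  crf$theta[, 3, 2] <- c(2, 3)   # START -> B scores 5
  expect_equal(sequence_score(crf, ctx, "A"), 2)
  expect_equal(sequence_score(crf, ctx, "B"), 5)
  expect_error(sequence_score(crf, ctx, "Z"), class = "nerlstm_value_error")

  # random instance equals an explicit loop over positions
  set.seed(14)
  crf2 <- random_crf(c("A", "B", "C"), 4)
  ctx2 <- matrix(rnorm(20), 5, 4)
  tags <- c("B", "A", "C", "C", "B")
  ids <- match(tags, crf2$labels)
  prev <- c(4L, ids[-5])
  manual <- sum(vapply(1:5, function(t) {
    sum(crf2$theta[, prev[t], ids[t]] * ctx2[t, ])
  }, numeric(1)))
  expect_equal(sequence_score(crf2, ctx2, tags), manual, tolerance = 1e-12)
})

test_that("log-partition has its closed forms at n = 1 and at zero weights", {
  set.seed(3)
  crf <- random_crf(c("A", "B", "C"), 3)
  ctx <- matrix(rnorm(3), 1, 3)
  s <- vapply(c("A", "B", "C"), function(y) sequence_score(crf, ctx, y),
              numeric(1))
  expect_equal(log_partition(crf, ctx), log(sum(exp(s))), tolerance = 1e-12)

  crf0 <- crf_params(c("A", "B", "C"), 3)
  ctx4 <- matrix(rnorm(12), 4, 3)
  expect_equal(log_partition(crf0, ctx4), 4 * log(3), tolerance = 1e-12)
  expect_equal(crf_log_likelihood(crf0, ctx4, c("A", "B", "C", "A")),
               -4 * log(3), tolerance = 1e-12)
})

test_that("forward recursion agrees with brute-force enumeration", {
  set.seed(90)
  for (param in c("pairvec", "factored")) {
    for (rep in 1:10) {
      k <- sample(2:4, 1); n <- sample(1:5, 1); D <- sample(2:5, 1)
      crf <- random_crf(paste0("L", seq_len(k)), D, parameterization = param)
      ctx <- matrix(rnorm(n * D), n, D)
      enum <- enumerate_scores(crf, ctx)
      expect_equal(log_partition(crf, ctx),
                   max(enum$scores) + log(sum(exp(enum$scores - max(enum$scores)))),
                   tolerance = 1e-10)
      # probabilities over all sequences sum to 1
      lls <- enum$scores - log_partition(crf, ctx)
      expect_equal(sum(exp(lls)), 1, tolerance = 1e-9)
      # forward and backward recursions agree on the normalizer
      S <- nerlstm:::crf_lattice(crf, ctx)
      beta <- nerlstm:::crf_backward(S)
      lz_b <- nerlstm:::logsumexp(S[1, k + 1, ] + beta[1, ])
      expect_equal(lz_b, log_partition(crf, ctx), tolerance = 1e-10)
    }
  }
})

test_that("the log-likelihood is shift-invariant in the transition vectors", {
  set.seed(8)
  crf <- random_crf(c("A", "B"), 3)
  ctx <- matrix(rnorm(9), 3, 3)
  tags <- c("A", "B", "B")
  base <- crf_log_likelihood(crf, ctx, tags)
  shift <- crf
  shift$theta <- sweep(shift$theta, 1, c(0.7, -1.1, 0.3), "+")
  expect_equal(crf_log_likelihood(shift, ctx, tags), base, tolerance = 1e-10)
})

test_that("Viterbi attains the brute-force maximum and breaks ties low", {
  set.seed(71)
  for (rep in 1:30) {
    k <- sample(2:5, 1); n <- sample(1:6, 1); D <- sample(2:4, 1)
    param <- if (rep %% 2) "pairvec" else "factored"
    crf <- random_crf(paste0("L", seq_len(k)), D, parameterization = param)
    ctx <- matrix(rnorm(n * D), n, D)
    enum <- enumerate_scores(crf, ctx)
    vb <- viterbi_decode(crf, ctx)
    expect_equal(vb$score, max(enum$scores), tolerance = 1e-10)
    expect_equal(sequence_score(crf, ctx, vb$tags), vb$score, tolerance = 1e-10)
    # decoded score never below the gold-path score
    gold <- crf$labels[sample(k, n, TRUE)]
    expect_gte(vb$score + 1e-12, sequence_score(crf, ctx, gold))
  }

  # uniform lattice: every sequence ties; the first label wins throughout
  crf0 <- crf_params(c("A", "B", "C"), 3)
  vb <- viterbi_decode(crf0, matrix(rnorm(9), 3, 3))
  expect_equal(vb$tags, c("A", "A", "A"))
  expect_equal(vb$score, 0)
})

test_that("CRF gradients match central finite differences", {
  set.seed(23)
  eps <- 1e-5
  for (param in c("pairvec", "factored")) {
    crf <- random_crf(c("A", "B", "C"), 4, parameterization = param)
    ctx <- matrix(rnorm(16), 4, 4)
    tags <- c("B", "A", "C", "B")
    cg <- crf_gradients(crf, ctx, tags)
    nms <- if (param == "pairvec") "theta" else c("W", "A")
    for (nm in nms) {
      g <- cg$grads[[nm]]
      for (i in seq_along(crf[[nm]])) {
        cp <- crf; cp[[nm]][i] <- cp[[nm]][i] + eps
        cm <- crf; cm[[nm]][i] <- cm[[nm]][i] - eps
        fd <- (crf_log_likelihood(cp, ctx, tags) -
                 crf_log_likelihood(cm, ctx, tags)) / (2 * eps)
        expect_lt(abs(fd - g[i]) / max(1e-8, abs(fd) + abs(g[i])), 1e-4)
      }
    }
    for (i in seq_along(ctx)) {
      xp <- ctx; xp[i] <- xp[i] + eps
      xm <- ctx; xm[i] <- xm[i] - eps
      fd <- (crf_log_likelihood(crf, xp, tags) -
               crf_log_likelihood(crf, xm, tags)) / (2 * eps)
      expect_lt(abs(fd - cg$dContext[i]) /
                  max(1e-8, abs(fd) + abs(cg$dContext[i])), 1e-4)
    }
  }
})

test_that("marginals are proper distributions, uniform at zero weights", {
  set.seed(5)
  crf0 <- crf_params(c("A", "B", "C", "D"), 3)
  ctx <- matrix(rnorm(9), 3, 3)
  cg <- crf_gradients(crf0, ctx, c("A", "B", "C"))
  expect_equal(cg$marginals, matrix(0.25, 3, 4), tolerance = 1e-12)

  crf <- random_crf(c("A", "B", "C"), 3)
  cg2 <- crf_gradients(crf, ctx, c("A", "B", "C"))
  expect_equal(rowSums(cg2$marginals), rep(1, 3), tolerance = 1e-10)
})

test_that("a saturated model has vanishing gradient on its own argmax", {
  set.seed(33)
  crf <- random_crf(c("A", "B"), 3)
  ctx <- matrix(rnorm(12), 4, 3)
  best <- viterbi_decode(crf, ctx)$tags
  crf$theta <- crf$theta * 1e3  # decisive distribution on the argmax path
  cg <- crf_gradients(crf, ctx, best)
  expect_lt(sqrt(sum(cg$grads$theta^2) + sum(cg$dContext^2)), 1e-6)
  expect_gt(exp(crf_log_likelihood(crf, ctx, best)), 1 - 1e-9)
})

test_that("softmax decoding is position-wise argmax without transitions", {
  set.seed(44)
  labels <- c("A", "B", "C")
  W <- matrix(rnorm(9), 3, 3)
  ctx <- matrix(rnorm(15), 5, 3)
  tags <- softmax_decode(W, ctx, labels)
  manual <- labels[vapply(1:5, function(t) which.max(drop(W %*% ctx[t, ])),
                          integer(1))]
  expect_equal(tags, manual)

  # n = 1: agrees with Viterbi whose start transitions carry the same weights
  crf <- crf_params(labels, 3)
  for (y in 1:3) crf$theta[, 4, y] <- W[y, ]
  ctx1 <- matrix(rnorm(3), 1, 3)
  expect_equal(softmax_decode(W, ctx1, labels), viterbi_decode(crf, ctx1)$tags)

  # may emit invalid BIOES sequences; decoding repairs downstream
  bl <- bioes_labels("x")
  Wb <- matrix(0, 5, 2); Wb[match("I-x", bl), ] <- 1
  invalid <- softmax_decode(Wb, matrix(1, 3, 2), bl)
  expect_false(is_valid_bioes(invalid))
  expect_equal(nrow(decode_bioes(toy_tokens(c("a", "b", "c")), invalid)), 1L)
})

test_that("the hard transition mask forbids invalid BIOES decodes", {
  set.seed(58)
  labels <- bioes_labels("x")
  crf <- crf_params(labels, 3, mask_invalid = TRUE)
  crf$theta[] <- rnorm(length(crf$theta))
  ctx <- matrix(rnorm(12), 4, 3)
  vb <- viterbi_decode(crf, ctx)
  # every decoded transition (incl. START) is structurally allowed; the
  # mask is transition-local, so entity closure at sentence end is still
  # the BIOES repair step's job
  M <- bioes_transition_mask(labels)
  ids <- match(vb$tags, labels)
  prev <- c(length(labels) + 1L, ids[-length(ids)])
  expect_true(all(M[cbind(prev, ids)] == 0))
  expect_equal(M[length(labels) + 1, match("I-x", labels)], -1e30)
  expect_equal(M[match("B-x", labels), match("E-x", labels)], 0)
})
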