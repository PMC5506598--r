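# Linear-chain CRF inference layer.
#
# The distinctive parameterization scores position t of a label sequence by
# a full weight vector per ordered label transition dotted with the encoder
# output: score(y, h) = sum_t theta[y_{t-1}, y_t] . h_t, with y_0 a
# distinguished START symbol and no STOP term. The conditional probability
# is exp(score) normalized over all label sequences; the normalizer is
# computed by the forward algorithm in log space, decoding by Viterbi.
# A conventional factored form (per-label emission vector + scalar
# transition weights) is available for comparison.

#' Create CRF parameters
#'
#' @param labels Character vector of emitted labels (e.g. from
#'   [bioes_labels()]); a START symbol is handled internally and is not part
#'   of this set.
#' @param width Width of the encoder context vectors (2H for a bi-LSTM).
#' @param parameterization `"pairvec"` (default): one weight vector of length
#'   `width` per ordered pair (previous label incl. START, current label).
#'   `"factored"`: per-label emission vector plus a scalar transition matrix.
#' @param mask_invalid Add a hard mask that forbids structurally invalid
#'   BIOES transitions during scoring and decoding (default `FALSE`; invalid
#'   model output is repaired at BIOES decoding instead).
#' @return A `crf_params` object. All weights start at zero: the encoder
#'   output h varies by position, so zero init is symmetric but not
#'   degenerate.
#' @export
crf_params <- function(labels, width,
                       parameterization = c("pairvec", "factored"),
                       mask_invalid = FALSE) {
  parameterization <- match.arg(parameterization)
  k <- length(labels)
  stopifnot(k >= 1, width >= 1, !anyDuplicated(labels))
  obj <- list(labels = labels, width = width,
              parameterization = parameterization,
              mask = if (mask_invalid) bioes_transition_mask(labels) else NULL)
  if (parameterization == "pairvec") {
    obj$theta <- array(0, dim = c(width, k + 1L, k))  # [., y_prev (k+1=START), y]
  } else {
    obj$W <- matrix(0, k, width)
    obj$A <- matrix(0, k + 1L, k)
  }
  structure(obj, class = "crf_params")
}

#' Additive mask of structurally invalid BIOES transitions
#'
#' Entry `[y', y]` is 0 when `y' -> y` can occur in a valid BIOES sequence
#' and a large negative number otherwise (row `k+1` is the START symbol).
#'
#' @param labels BIOES label inventory.
#' @return `(k+1) x k` numeric matrix.
#' @export
bioes_transition_mask <- function(labels) {
  k <- length(labels)
  kind <- ifelse(labels == "O", "O", substr(labels, 1, 1))
  type <- ifelse(labels == "O", "", substring(labels, 3))
  M <- matrix(-1e30, k + 1L, k)
  # "open" states (B-t, I-t) may only be followed by I-t / E-t of the same
  # type; "closed" states (O, E-*, S-*, START) by O / B-* / S-*.
  for (yp in seq_len(k + 1L)) {
    open_type <- if (yp <= k && kind[yp] %in% c("B", "I")) type[yp] else NA
    for (y in seq_len(k)) {
      ok <- if (is.na(open_type)) kind[y] %in% c("O", "B", "S")
            else kind[y] %in% c("I", "E") && type[y] == open_type
      if (ok) M[yp, y] <- 0
    }
  }
  M
}

# Score lattice: array S[t, y_prev, y] = transition-specific score at t.
# Row k+1 of the y_prev axis is START (only meaningful at t = 1).
crf_lattice <- function(params, context) {
  n <- nrow(context); k <- length(params$labels)
  if (ncol(context) != params$width) {
    abort_nerlstm(sprintf("context width %d, expected %d",
                          ncol(context), params$width), "nerlstm_shape_error")
  }
  if (params$parameterization == "pairvec") {
    E <- context %*% matrix(params$theta, params$width, (k + 1L) * k)
    S <- array(E, dim = c(n, k + 1L, k))
  } else {
    Em <- context %*% t(params$W)                 # n x k
    S <- array(0, dim = c(n, k + 1L, k))
    for (t in seq_len(n)) {
      S[t, , ] <- matrix(Em[t, ], k + 1L, k, byrow = TRUE) + params$A
    }
  }
  if (!is.null(params$mask)) {
    for (t in seq_len(n)) S[t, , ] <- S[t, , ] + params$mask
  }
  S
}

label_ids <- function(params, tags) {
  ids <- match(tags, params$labels)
  if (anyNA(ids)) {
    abort_nerlstm(sprintf("unknown label(s): %s",
                          paste(unique(tags[is.na(ids)]), collapse = ", ")),
                  "nerlstm_value_error")
  }
  ids
}

#' Unnormalized score of a label sequence
#'
#' `sum_t theta[y_{t-1}, y_t] . h_t` in log space (no exponentiation), with
#' `y_0` the START symbol.
#'
#' @param params A `crf_params` object.
#' @param context Encoder output matrix (n x width).
#' @param tags Character vector of n labels.
#' @return Scalar score.
#' @export
sequence_score <- function(params, context, tags) {
  n <- nrow(context)
  stopifnot(length(tags) == n)
  ids <- label_ids(params, tags)
  S <- crf_lattice(params, context)
  k <- length(params$labels)
  prev <- c(k + 1L, ids[-n])
  sum(S[cbind(seq_len(n), prev, ids)])
}

#' Log-partition function of the CRF
#'
#' `log sum over all label sequences of exp(sequence_score)`, computed by the
#' forward recursion with a log-sum-exp at every step.
#'
#' @inheritParams sequence_score
#' @return Scalar log-normalizer.
#' @export
log_partition <- function(params, context) {
  S <- crf_lattice(params, context)
  logsumexp(crf_forward(S))
}

# forward recursion; returns alpha[n, ] (log scores ending in each label)
crf_forward <- function(S) {
  n <- dim(S)[1]; k <- dim(S)[3]
  alpha <- S[1, k + 1L, ]
  if (n > 1) for (t in 2:n) {
    alpha <- vapply(seq_len(k), function(y) logsumexp(alpha + S[t, 1:k, y]),
                    numeric(1))
  }
  alpha
}

# backward recursion; returns full beta matrix (n x k)
crf_backward <- function(S) {
  n <- dim(S)[1]; k <- dim(S)[3]
  beta <- matrix(0, n, k)
  if (n > 1) for (t in (n - 1):1) {
    beta[t, ] <- vapply(seq_len(k), function(yp) {
      logsumexp(S[t + 1L, yp, ] + beta[t + 1L, ])
    }, numeric(1))
  }
  beta
}

#' Conditional log-likelihood of a label sequence
#'
#' `sequence_score - log_partition`; always <= 0.
#'
#' @inheritParams sequence_score
#' @return Scalar log-probability.
#' @export
crf_log_likelihood <- function(params, context, tags) {
  sequence_score(params, context, tags) - log_partition(params, context)
}

#' Viterbi decoding
#'
#' Returns a label sequence maximizing the unnormalized score (equivalently
#' the conditional probability) together with that score. Ties are broken
#' towards the lowest label index at every backtracking step.
#'
#' @inheritParams sequence_score
#' @return List with `tags` (character vector) and `score` (scalar).
#' @export
viterbi_decode <- function(params, context) {
  S <- crf_lattice(params, context)
  n <- dim(S)[1]; k <- dim(S)[3]
  delta <- S[1, k + 1L, ]
  ptr <- matrix(0L, n, k)
  if (n > 1) for (t in 2:n) {
    new_delta <- numeric(k)
    for (y in seq_len(k)) {
      cand <- delta + S[t, 1:k, y]
      best <- which.max(cand)                    # first index on ties
      ptr[t, y] <- best
      new_delta[y] <- cand[best]
    }
    delta <- new_delta
  }
  y <- integer(n)
  y[n] <- which.max(delta)
  score <- delta[y[n]]
  if (n > 1) for (t in n:2) y[t - 1L] <- ptr[t, y[t]]
  list(tags = params$labels[y], score = score)
}

#' Gradients of the CRF log-likelihood
#'
#' Empirical minus expected transition features, with expectations from the
#' forward-backward pairwise marginals. Gradients are of the log-likelihood
#' (ascent direction); a trainer minimizing the negative log-likelihood
#' negates them.
#'
#' @inheritParams sequence_score
#' @return List with `grads` (parameter-shaped: `theta`, or `W` and `A`),
#'   `dContext` (n x width gradient w.r.t. the encoder output),
#'   `marginals` (n x k per-position posterior label probabilities) and
#'   `loglik` (the conditional log-likelihood, shared with the same pass).
#' @export
crf_gradients <- function(params, context, tags) {
  S <- crf_lattice(params, context)
  n <- dim(S)[1]; k <- dim(S)[3]
  ids <- label_ids(params, tags)
  stopifnot(length(ids) == n)
  alpha <- matrix(0, n, k)
  alpha[1, ] <- S[1, k + 1L, ]
  if (n > 1) for (t in 2:n) {
    alpha[t, ] <- vapply(seq_len(k), function(y) {
      logsumexp(alpha[t - 1L, ] + S[t, 1:k, y])
    }, numeric(1))
  }
  logZ <- logsumexp(alpha[n, ])
  beta <- crf_backward(S)
  gold <- sum(S[cbind(seq_len(n), c(k + 1L, ids[-n]), ids)])

  # D[t, y', y] = empirical(t) - pairwise marginal(t); START row at t = 1
  D <- array(0, dim = c(n, k + 1L, k))
  marg <- matrix(0, n, k)
  p1 <- exp(S[1, k + 1L, ] + beta[1, ] - logZ)
  marg[1, ] <- p1
  D[1, k + 1L, ] <- -p1
  D[1, k + 1L, ids[1]] <- D[1, k + 1L, ids[1]] + 1
  if (n > 1) for (t in 2:n) {
    M <- exp(outer(alpha[t - 1L, ], beta[t, ], "+") + S[t, 1:k, ] - logZ)
    marg[t, ] <- colSums(M)
    D[t, 1:k, ] <- -M
    D[t, ids[t - 1L], ids[t]] <- D[t, ids[t - 1L], ids[t]] + 1
  }

  Dflat <- matrix(D, n, (k + 1L) * k)
  if (params$parameterization == "pairvec") {
    dtheta <- array(crossprod(context, Dflat), dim = dim(params$theta))
    dContext <- Dflat %*% t(matrix(params$theta, params$width, (k + 1L) * k))
    grads <- list(theta = dtheta)
  } else {
    Dcol <- t(apply(D, 1, function(m) colSums(matrix(m, k + 1L, k))))
    if (n == 1) Dcol <- matrix(Dcol, 1, k)
    dW <- crossprod(Dcol, context)
    dA <- matrix(colSums(Dflat), k + 1L, k)
    dContext <- Dcol %*% params$W
    grads <- list(W = dW, A = dA)
  }
  list(grads = grads, dContext = dContext, marginals = marg,
       loglik = gold - logZ)
}

#' Position-wise softmax decoding (non-structured baseline)
#'
#' Drops the interactions between successive labels: each position is
#' classified independently by `argmax_y w_y . h_t`. The result may violate
#' BIOES transition structure; [decode_bioes()] repairs it downstream.
#'
#' @param emission Weight matrix (k x width), one row per label.
#' @param context Encoder output matrix (n x width).
#' @param labels Character vector of k labels.
#' @return Character vector of n labels.
#' @export
softmax_decode <- function(emission, context, labels) {
  scores <- context %*% t(emission)
  labels[apply(scores, 1, which.max)]
}
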