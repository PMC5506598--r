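# Peephole LSTM core.
#
# Gates are stacked in blocks of the hidden size in the fixed order
# i (input), f (forget), g (cell candidate), o (output), so one matrix
# multiply per step serves all four. Peephole connections are element-wise
# (diagonal) vectors: the input and forget gates read c_{t-1}, the output
# gate reads c_t. Recurrences:
#
#   i_t = sigmoid(W_xi x_t + W_hi h_{t-1} + w_ci * c_{t-1} + b_i)
#   f_t = sigmoid(W_xf x_t + W_hf h_{t-1} + w_cf * c_{t-1} + b_f)
#   c_t = f_t * c_{t-1} + i_t * tanh(W_xc x_t + W_hc h_{t-1} + b_c)
#   o_t = sigmoid(W_xo x_t + W_ho h_{t-1} + w_co * c_t + b_o)
#   h_t = o_t * tanh(c_t)

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_limit <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Initialize peephole LSTM parameters
#'
#' Weight matrices are uniform in the symmetric Glorot range
#' `[-sqrt(6/(fan_in+fan_out)), +...]`; biases are zero except the forget
#' gate's, set to 1 so early training does not erase the cell state;
#' peephole vectors use the Glorot range for a square fan.
#'
#' @param input_dim Input vector size d.
#' @param hidden Hidden/cell size H.
#' @param seed Integer seed (same seed, same parameters).
#' @return A named list: `Wx` (4H x d), `Wh` (4H x H), peepholes `p_i`,
#'   `p_f`, `p_o` (length H), bias `b` (length 4H), plus `input_dim`,
#'   `hidden`.
#' @export
lstm_params <- function(input_dim, hidden, seed) {
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  H <- hidden
  lim_x <- glorot_limit(input_dim, H)
  lim_h <- glorot_limit(H, H)
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget bias
  list(
    Wx = matrix(stats::runif(4 * H * input_dim, -lim_x, lim_x), 4 * H, input_dim),
    Wh = matrix(stats::runif(4 * H * H, -lim_h, lim_h), 4 * H, H),
    p_i = stats::runif(H, -lim_h, lim_h),
    p_f = stats::runif(H, -lim_h, lim_h),
    p_o = stats::runif(H, -lim_h, lim_h),
    b = b,
    input_dim = input_dim, hidden = H
  )
}

#' One LSTM step
#'
#' Applies the peephole recurrences once. This is the reference entry point
#' for the unit; sequence code uses the same arithmetic with the input
#' projections batched.
#'
#' @param params Parameters from [lstm_params()].
#' @param x_t Input vector (length `input_dim`).
#' @param prev List with `h` and `c` vectors (length `hidden`).
#' @return List with new `h` and `c`.
#' @export
lstm_step <- function(params, x_t, prev) {
  H <- params$hidden
  if (length(x_t) != params$input_dim) {
    abort_nerlstm(sprintf("input length %d, expected %d",
                          length(x_t), params$input_dim), "nerlstm_shape_error")
  }
  if (length(prev$h) != H || length(prev$c) != H) {
    abort_nerlstm("state size mismatch", "nerlstm_shape_error")
  }
  z <- drop(params$Wx %*% x_t + params$Wh %*% prev$h) + params$b
  i <- sigmoid(z[1:H] + params$p_i * prev$c)
  f <- sigmoid(z[(H + 1):(2 * H)] + params$p_f * prev$c)
  g <- tanh(z[(2 * H + 1):(3 * H)])
  c_new <- f * prev$c + i * g
  o <- sigmoid(z[(3 * H + 1):(4 * H)] + params$p_o * c_new)
  list(h = o * tanh(c_new), c = c_new)
}

# Forward pass over a sequence with cache for backpropagation.
# X: n x d matrix. Returns H (n x H), C, and the cache.
lstm_forward <- function(params, X) {
  H <- params$hidden; n <- nrow(X)
  if (ncol(X) != params$input_dim) {
    abort_nerlstm(sprintf("input width %d, expected %d",
                          ncol(X), params$input_dim), "nerlstm_shape_error")
  }
  A <- X %*% t(params$Wx)                     # n x 4H, batched input projection
  A <- sweep(A, 2, params$b, "+")
  Hm <- matrix(0, n, H); Cm <- matrix(0, n, H)
  Im <- matrix(0, n, H); Fm <- matrix(0, n, H)
  Gm <- matrix(0, n, H); Om <- matrix(0, n, H)
  Hprev <- matrix(0, n, H); Cprev <- matrix(0, n, H)
  h <- rep(0, H); cc <- rep(0, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in seq_len(n)) {
    Hprev[t, ] <- h; Cprev[t, ] <- cc
    z <- A[t, ] + drop(params$Wh %*% h)
    i <- sigmoid(z[i1] + params$p_i * cc)
    f <- sigmoid(z[i2] + params$p_f * cc)
    g <- tanh(z[i3])
    cc <- f * cc + i * g
    o <- sigmoid(z[i4] + params$p_o * cc)
    h <- o * tanh(cc)
    Im[t, ] <- i; Fm[t, ] <- f; Gm[t, ] <- g; Om[t, ] <- o
    Cm[t, ] <- cc; Hm[t, ] <- h
  }
  list(H = Hm, C = Cm,
       cache = list(X = X, I = Im, F = Fm, G = Gm, O = Om,
                    C = Cm, Cprev = Cprev, Hprev = Hprev, n = n, hidden = H))
}

# Backpropagation through time. dH: n x H upstream gradient on each h_t.
# Returns parameter gradients (same shapes as params) and dX.
lstm_backward <- function(params, cache, dH) {
  n <- cache$n; H <- cache$hidden
  Dpre <- matrix(0, n, 4 * H)
  dp_i <- rep(0, H); dp_f <- rep(0, H); dp_o <- rep(0, H)
  dh_rec <- rep(0, H); dc_rec <- rep(0, H)
  WhT <- t(params$Wh)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  for (t in n:1) {
    i <- cache$I[t, ]; f <- cache$F[t, ]; g <- cache$G[t, ]; o <- cache$O[t, ]
    ct <- cache$C[t, ]; cp <- cache$Cprev[t, ]
    tc <- tanh(ct)
    dh <- dH[t, ] + dh_rec
    do_pre <- dh * tc * o * (1 - o)
    dc <- dh * o * (1 - tc^2) + dc_rec + params$p_o * do_pre
    dg_pre <- dc * i * (1 - g^2)
    di_pre <- dc * g * i * (1 - i)
    df_pre <- dc * cp * f * (1 - f)
    dc_rec <- dc * f + params$p_i * di_pre + params$p_f * df_pre
    dp_o <- dp_o + do_pre * ct
    dp_i <- dp_i + di_pre * cp
    dp_f <- dp_f + df_pre * cp
    dpre <- c(di_pre, df_pre, dg_pre, do_pre)
    Dpre[t, ] <- dpre
    dh_rec <- drop(WhT %*% dpre)
  }
  list(
    grads = list(Wx = crossprod(Dpre, cache$X),
                 Wh = crossprod(Dpre, cache$Hprev),
                 p_i = dp_i, p_f = dp_f, p_o = dp_o,
                 b = colSums(Dpre)),
    dX = Dpre %*% params$Wx
  )
}

#' Bidirectional LSTM encoding of a sequence
#'
#' Runs a forward LSTM left to right and a backward LSTM over the reversed
#' sequence, both from zero initial states, and concatenates the two hidden
#' states at each position: row t of the context matrix is `[h_ft ; h_bt]`.
#'
#' @param params_fwd,params_bwd Parameter lists from [lstm_params()].
#' @param X Input matrix (n x d), n >= 1.
#' @param keep_cache Keep forward caches for training (internal use).
#' @return List with `context` (n x 2H) and, if requested, the caches.
#' @export
run_bilstm <- function(params_fwd, params_bwd, X, keep_cache = FALSE) {
  n <- nrow(X)
  if (is.null(n) || n < 1) abort_nerlstm("empty sequence", "nerlstm_value_error")
  fwd <- lstm_forward(params_fwd, X)
  bwd <- lstm_forward(params_bwd, X[n:1, , drop = FALSE])
  context <- cbind(fwd$H, bwd$H[n:1, , drop = FALSE])
  if (keep_cache) list(context = context, fwd = fwd, bwd = bwd)
  else list(context = context)
}

# Backward pass matching run_bilstm(keep_cache = TRUE).
bilstm_backward <- function(params_fwd, params_bwd, run, dContext) {
  n <- nrow(dContext); H <- params_fwd$hidden
  bf <- lstm_backward(params_fwd, run$fwd$cache, dContext[, 1:H, drop = FALSE])
  dHb <- dContext[n:1, (H + 1):(2 * H), drop = FALSE]
  bb <- lstm_backward(params_bwd, run$bwd$cache, dHb)
  list(fwd = bf$grads, bwd = bb$grads,
       dX = bf$dX + bb$dX[n:1, , drop = FALSE])
}

# character lookup: exact char else the UNK row (never lowercased)
char_indices <- function(char_table, word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  idx <- unname(char_table$index[chars])
  idx[is.na(idx)] <- char_table$unk_index
  idx
}

#' Character-level word representation from a bi-LSTM
#'
#' Embeds the character sequence of a word and returns the concatenation of
#' the final forward hidden state and the final backward hidden state (the
#' backward LSTM reads the characters reversed), a vector of length twice the
#' character LSTM size.
#'
#' @param char_table Character `embedding_table`.
#' @param params_fwd,params_bwd Character LSTM parameters.
#' @param word Non-empty string.
#' @param keep_cache Keep caches for training (internal use).
#' @return Numeric vector of length `2 * hidden` (or a list when
#'   `keep_cache`).
#' @export
char_repr_bilstm <- function(char_table, params_fwd, params_bwd, word,
                             keep_cache = FALSE) {
  if (!nzchar(word)) abort_nerlstm("empty word", "nerlstm_value_error")
  idx <- char_indices(char_table, word)
  E <- char_table$vectors[idx, , drop = FALSE]
  m <- nrow(E)
  fwd <- lstm_forward(params_fwd, E)
  bwd <- lstm_forward(params_bwd, E[m:1, , drop = FALSE])
  v <- c(fwd$H[m, ], bwd$H[m, ])
  if (keep_cache) list(v = v, idx = idx, fwd = fwd, bwd = bwd, m = m) else v
}

# Backward for char_repr_bilstm; dv has length 2 * hidden.
# Returns LSTM grads and sparse character-embedding row gradients.
char_repr_bilstm_backward <- function(params_fwd, params_bwd, cache, dv) {
  H <- params_fwd$hidden; m <- cache$m
  dHf <- matrix(0, m, H); dHf[m, ] <- dv[1:H]
  dHb <- matrix(0, m, H); dHb[m, ] <- dv[(H + 1):(2 * H)]
  bf <- lstm_backward(params_fwd, cache$fwd$cache, dHf)
  bb <- lstm_backward(params_bwd, cache$bwd$cache, dHb)
  dE <- bf$dX + bb$dX[m:1, , drop = FALSE]
  list(fwd = bf$grads, bwd = bb$grads, dE = dE, idx = cache$idx)
}

#' Initialize character CNN parameters
#'
#' A bank of `n_filters` width-`k` convolution kernels over character
#' embedding rows, with one bias per filter.
#'
#' @param char_dim Character embedding dimension.
#' @param k Odd filter width (window of characters seen at once).
#' @param n_filters Number of filters; also the output size.
#' @param seed Integer seed.
#' @return Named list: `W` (`n_filters` x `k*char_dim`), `b`, `k`, `char_dim`.
#' @export
char_cnn_params <- function(char_dim, k = 3, n_filters = 25, seed = 1) {
  if (k %% 2 == 0) abort_nerlstm("filter width k must be odd", "nerlstm_value_error")
  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  lim <- glorot_limit(k * char_dim, n_filters)
  list(W = matrix(stats::runif(n_filters * k * char_dim, -lim, lim),
                  n_filters, k * char_dim),
       b = rep(0, n_filters), k = k, char_dim = char_dim,
       n_filters = n_filters)
}

#' Character-level word representation from a CNN
#'
#' The character embedding sequence is zero-padded with `floor(k/2)` rows on
#' each side, each filter is slid across all positions (bias added to each
#' response), and responses are max-pooled over positions. No nonlinearity is
#' applied; the pooled responses are the representation.
#'
#' @param char_table Character `embedding_table`.
#' @param params Parameters from [char_cnn_params()].
#' @param word Non-empty string.
#' @param keep_cache Keep pooling argmax positions for training.
#' @return Numeric vector of length `n_filters` (or a list when
#'   `keep_cache`).
#' @export
char_repr_cnn <- function(char_table, params, word, keep_cache = FALSE) {
  if (!nzchar(word)) abort_nerlstm("empty word", "nerlstm_value_error")
  idx <- char_indices(char_table, word)
  E <- char_table$vectors[idx, , drop = FALSE]
  m <- nrow(E); dc <- ncol(E); k <- params$k; p <- k %/% 2
  P <- rbind(matrix(0, p, dc), E, matrix(0, p, dc))
  # window matrix: row q = flattened rows q..q+k-1 of P (column-major)
  Wmat <- matrix(0, m, k * dc)
  for (q in seq_len(m)) {
    Wmat[q, ] <- as.vector(P[q:(q + k - 1), , drop = FALSE])
  }
  R <- Wmat %*% t(params$W)                       # m x n_filters
  R <- sweep(R, 2, params$b, "+")
  arg <- apply(R, 2, which.max)                   # first max on ties
  v <- R[cbind(arg, seq_along(arg))]
  if (keep_cache) list(v = v, idx = idx, arg = arg, Wmat = Wmat, m = m) else v
}

# Backward for char_repr_cnn; dv has length n_filters.
char_repr_cnn_backward <- function(params, cache, dv) {
  k <- params$k; dc <- params$char_dim; m <- cache$m; p <- k %/% 2
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  dP <- matrix(0, m + 2 * p, dc)
  for (j in seq_along(dv)) {
    q <- cache$arg[j]
    dW[j, ] <- dv[j] * cache$Wmat[q, ]
    dP[q:(q + k - 1), ] <- dP[q:(q + k - 1), ] +
      dv[j] * matrix(params$W[j, ], k, dc)
    }
  dE <- dP[(p + 1):(p + m), , drop = FALSE]
  list(W = dW, b = dv, dE = dE, idx = cache$idx)
}

#' Inverted dropout
#'
#' During training each entry is zeroed independently with probability
#' `rate` and survivors are scaled by `1/(1-rate)`, so the expected value is
#' unchanged and inference needs no rescaling. At `training = FALSE` (or
#' `rate = 0`) the input is returned unchanged.
#'
#' @param x Numeric matrix or vector.
#' @param rate Drop probability in `[0, 1)`.
#' @param training Apply dropout (`TRUE`) or pass through (`FALSE`).
#' @param seed Optional seed for the mask (otherwise the current RNG stream
#'   is used, which is how training draws its masks).
#' @param return_mask Also return the multiplicative mask (internal use).
#' @return `x` with dropout applied, or a list `(x, mask)`.
#' @export
apply_dropout <- function(x, rate, training = TRUE, seed = NULL,
                          return_mask = FALSE) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    abort_nerlstm("dropout rate must be in [0, 1)", "nerlstm_value_error")
  }
  if (!training || rate == 0) {
    if (return_mask) return(list(x = x, mask = array(1, dim = dim(x) %||% length(x))))
    return(x)
  }
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  keep <- (stats::runif(length(x)) >= rate) / (1 - rate)
  mask <- x; mask[] <- keep
  out <- x * mask
  if (return_mask) list(x = out, mask = mask) else out
}
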