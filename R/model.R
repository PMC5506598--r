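# Model assembly: input layer (token + character representations),
# bidirectional LSTM encoder, CRF inference layer, and the per-sentence
# forward/backward pass used by the trainer.

#' Training and architecture configuration
#'
#' Defaults are the hyperparameters the architecture was designed with:
#' token embedding dimension 50, character embedding dimension 25,
#' character LSTM size 25, character CNN filter width 3 with 25 filters,
#' token-level LSTM size 100, dropout probability 0.5, learning rate 0.005,
#' gradient clipping 5.0, and 50 training epochs (30 or 55 suit the other
#' reference tasks; the count is a plain config knob).
#'
#' @param token_dim Token embedding dimension.
#' @param char_dim Character embedding dimension.
#' @param char_lstm_size Character bi-LSTM hidden size (per direction).
#' @param char_cnn_filter_size Character CNN filter width (odd).
#' @param char_cnn_filter_number Character CNN filter count.
#' @param token_lstm_size Token-level bi-LSTM hidden size (per direction).
#' @param dropout Dropout probability in `[0, 1)`.
#' @param learning_rate SGD step size.
#' @param clip Global gradient-norm clipping threshold.
#' @param epochs Number of training epochs.
#' @param lowercase_backoff Lowercase back-off at token lookup.
#' @param crf_parameterization `"pairvec"` or `"factored"` (see
#'   [crf_params()]).
#' @param mask_invalid Hard-mask invalid BIOES transitions in the CRF.
#' @param shuffle Shuffle sentences every epoch.
#' @param seed Master integer seed for initialization, shuffling and dropout.
#' @return A named list of class `ner_config`.
#' @export
ner_config <- function(token_dim = 50, char_dim = 25, char_lstm_size = 25,
                       char_cnn_filter_size = 3, char_cnn_filter_number = 25,
                       token_lstm_size = 100, dropout = 0.5,
                       learning_rate = 0.005, clip = 5.0, epochs = 50,
                       lowercase_backoff = TRUE,
                       crf_parameterization = "pairvec",
                       mask_invalid = FALSE, shuffle = TRUE, seed = 1L) {
  stopifnot(learning_rate >= 0, clip > 0, epochs >= 1,
            dropout >= 0, dropout < 1)
  structure(list(
    token_dim = token_dim, char_dim = char_dim,
    char_lstm_size = char_lstm_size,
    char_cnn_filter_size = char_cnn_filter_size,
    char_cnn_filter_number = char_cnn_filter_number,
    token_lstm_size = token_lstm_size, dropout = dropout,
    learning_rate = learning_rate, clip = clip, epochs = epochs,
    lowercase_backoff = lowercase_backoff,
    crf_parameterization = crf_parameterization,
    mask_invalid = mask_invalid, shuffle = shuffle,
    seed = as.integer(seed)
  ), class = "ner_config")
}

mode_names <- c("token", "char-lstm", "char-cnn", "both")

mode_uses_char_lstm <- function(mode) mode %in% c("char-lstm", "both")
mode_uses_char_cnn <- function(mode) mode %in% c("char-cnn", "both")

input_width <- function(model) {
  cfg <- model$config
  w <- cfg$token_dim
  if (mode_uses_char_lstm(model$mode)) w <- w + 2 * cfg$char_lstm_size
  if (mode_uses_char_cnn(model$mode)) w <- w + cfg$char_cnn_filter_number
  w
}

#' Initialize an untrained recognizer
#'
#' Builds all parameters for the chosen input mode from a vocabulary, a
#' character alphabet and an entity type inventory. [ner_train()] calls this
#' internally; it is exported so the architecture can be probed directly.
#'
#' @param types Character vector of entity type names.
#' @param vocab Token vocabulary (character vector).
#' @param alphabet Character alphabet (character vector of single
#'   characters).
#' @param mode Input representation: `"token"` (token embeddings only),
#'   `"char-lstm"`, `"char-cnn"`, or `"both"`.
#' @param config An [ner_config()].
#' @param embeddings Optional pre-trained token `embedding_table` (e.g. from
#'   [load_word2vec_text()]); otherwise a seeded uniform random table is
#'   used. Fine-tuned during training either way.
#' @return An object of class `ner_model`.
#' @export
ner_model <- function(types, vocab, alphabet, mode = "token",
                      config = ner_config(), embeddings = NULL) {
  if (!mode %in% mode_names) {
    abort_nerlstm(sprintf("unknown mode '%s' (use %s)", mode,
                          paste(mode_names, collapse = ", ")),
                  "nerlstm_value_error")
  }
  seed <- config$seed
  token_table <- embeddings %||%
    init_random_table(vocab, config$token_dim, derive_seed(seed, 1))
  if (!is.null(embeddings)) config$token_dim <- embeddings$dim
  char_table <- init_random_table(alphabet, config$char_dim,
                                  derive_seed(seed, 2), -1, 1)
  model <- list(mode = mode, config = config, types = types,
                labels = bioes_labels(types),
                token_table = token_table, char_table = char_table)
  class(model) <- "ner_model"
  d_in <- input_width(model)
  model$tok_fwd <- lstm_params(d_in, config$token_lstm_size, derive_seed(seed, 3))
  model$tok_bwd <- lstm_params(d_in, config$token_lstm_size, derive_seed(seed, 4))
  if (mode_uses_char_lstm(mode)) {
    model$char_fwd <- lstm_params(config$char_dim, config$char_lstm_size,
                                  derive_seed(seed, 5))
    model$char_bwd <- lstm_params(config$char_dim, config$char_lstm_size,
                                  derive_seed(seed, 6))
  }
  if (mode_uses_char_cnn(mode)) {
    model$cnn <- char_cnn_params(config$char_dim, config$char_cnn_filter_size,
                                 config$char_cnn_filter_number,
                                 derive_seed(seed, 7))
  }
  model$crf <- crf_params(model$labels, 2 * config$token_lstm_size,
                          parameterization = config$crf_parameterization,
                          mask_invalid = config$mask_invalid)
  model$epoch_log <- tibble::tibble(epoch = integer(), mean_nll = numeric(),
                                    dev_exact_f1 = numeric())
  model
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf(paste0("<ner_model: mode %s, %d labels (%d types), ",
                     "vocab %d, input width %d, encoder 2x%d>\n"),
              x$mode, length(x$labels), length(x$types),
              length(x$token_table$index) - 2L, input_width(x),
              x$config$token_lstm_size))
  if (nrow(x$epoch_log) > 0) {
    cat(sprintf("  trained %d epochs, final mean NLL %.4f\n",
                max(x$epoch_log$epoch),
                x$epoch_log$mean_nll[nrow(x$epoch_log)]))
  }
  invisible(x)
}

#' Word-representation input matrix for a sentence
#'
#' Row t is the concatenation of the token-level embedding of word t and the
#' character-level vector(s) selected by the model's mode. Under the default
#' dimensions the widths are 50 (token), 100 (+char-lstm), 75 (+char-cnn)
#' and 125 (both).
#'
#' @param model An `ner_model`.
#' @param tokens Character vector of token surfaces (or a tokens tibble).
#' @return Numeric matrix, n x input width.
#' @export
build_word_inputs <- function(model, tokens) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  fw <- forward_inputs(model, tokens, keep_cache = FALSE)
  fw$X
}

# Input layer forward pass. Returns X and (optionally) per-word caches.
forward_inputs <- function(model, tokens, keep_cache = TRUE) {
  cfg <- model$config
  idx <- lookup_indices(model$token_table, tokens, cfg$lowercase_backoff)
  parts <- list(model$token_table$vectors[idx, , drop = FALSE])
  cl_caches <- NULL; cc_caches <- NULL
  if (mode_uses_char_lstm(model$mode)) {
    cl_caches <- lapply(tokens, function(w) {
      char_repr_bilstm(model$char_table, model$char_fwd, model$char_bwd, w,
                       keep_cache = keep_cache)
    })
    vs <- if (keep_cache) lapply(cl_caches, `[[`, "v") else cl_caches
    parts <- c(parts, list(do.call(rbind, vs)))
  }
  if (mode_uses_char_cnn(model$mode)) {
    cc_caches <- lapply(tokens, function(w) {
      char_repr_cnn(model$char_table, model$cnn, w, keep_cache = keep_cache)
    })
    vs <- if (keep_cache) lapply(cc_caches, `[[`, "v") else cc_caches
    parts <- c(parts, list(do.call(rbind, vs)))
  }
  list(X = do.call(cbind, parts), tok_idx = idx,
       cl = cl_caches, cc = cc_caches)
}

# Full forward + backward pass for one sentence.
# Returns nll and gradients of the nll for every parameter group, with
# embedding gradients as sparse (idx, rows) pairs.
sentence_grads <- function(model, tokens, tags, training = TRUE) {
  cfg <- model$config
  fin <- forward_inputs(model, tokens, keep_cache = TRUE)
  din <- apply_dropout(fin$X, cfg$dropout, training = training,
                       return_mask = TRUE)
  run <- run_bilstm(model$tok_fwd, model$tok_bwd, din$x, keep_cache = TRUE)
  dctx <- apply_dropout(run$context, cfg$dropout, training = training,
                        return_mask = TRUE)
  cg <- crf_gradients(model$crf, dctx$x, tags)
  nll <- -cg$loglik

  dContext <- -cg$dContext * dctx$mask
  bi <- bilstm_backward(model$tok_fwd, model$tok_bwd, run, dContext)
  dX <- bi$dX * din$mask

  n <- length(tokens)
  dt <- cfg$token_dim
  grads <- list(
    crf = lapply(cg$grads, function(g) -g),
    tok_fwd = bi$fwd, tok_bwd = bi$bwd,
    token_emb = list(idx = fin$tok_idx, G = dX[, 1:dt, drop = FALSE])
  )
  col <- dt
  char_idx <- integer(0); char_G <- NULL
  if (mode_uses_char_lstm(model$mode)) {
    w <- 2 * cfg$char_lstm_size
    acc_f <- NULL; acc_b <- NULL
    for (t in seq_len(n)) {
      bk <- char_repr_bilstm_backward(model$char_fwd, model$char_bwd,
                                      fin$cl[[t]], dX[t, (col + 1):(col + w)])
      acc_f <- add_grads(acc_f, bk$fwd)
      acc_b <- add_grads(acc_b, bk$bwd)
      char_idx <- c(char_idx, bk$idx)
      char_G <- rbind(char_G, bk$dE)
    }
    grads$char_fwd <- acc_f; grads$char_bwd <- acc_b
    col <- col + w
  }
  if (mode_uses_char_cnn(model$mode)) {
    w <- cfg$char_cnn_filter_number
    acc <- NULL
    for (t in seq_len(n)) {
      bk <- char_repr_cnn_backward(model$cnn, fin$cc[[t]],
                                   dX[t, (col + 1):(col + w)])
      acc <- add_grads(acc, list(W = bk$W, b = bk$b))
      char_idx <- c(char_idx, bk$idx)
      char_G <- rbind(char_G, bk$dE)
    }
    grads$cnn <- acc
  }
  if (length(char_idx) > 0) {
    grads$char_emb <- list(idx = char_idx, G = char_G)
  }
  list(nll = nll, grads = grads)
}

# recursive add over parameter-shaped lists (NULL acts as zero)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in names(b)) if (is.numeric(b[[nm]])) a[[nm]] <- a[[nm]] + b[[nm]]
    return(a)
  }
  a + b
}

# sum of squares over every gradient leaf; integer leaves are row indices
# of sparse embedding gradients, not gradients, and are skipped
grad_sumsq <- function(g) {
  if (is.integer(g)) return(0)
  if (is.numeric(g)) return(sum(g^2))
  if (is.list(g)) return(sum(vapply(g, grad_sumsq, numeric(1))))
  0
}

# scale every gradient leaf (indices pass through untouched)
grad_scale <- function(g, s) {
  if (is.integer(g)) return(g)
  if (is.numeric(g)) return(g * s)
  if (is.list(g)) return(lapply(g, grad_scale, s = s))
  g
}

#' Clip a gradient collection by its global L2 norm
#'
#' If the global norm over every numeric entry exceeds `max_norm`, all
#' gradients are scaled by `max_norm / norm`; otherwise they are returned
#' unchanged. Direction is always preserved.
#'
#' @param grads Arbitrarily nested list of numeric arrays.
#' @param max_norm Positive clipping threshold.
#' @return The (possibly rescaled) collection.
#' @export
clip_gradients <- function(grads, max_norm) {
  stopifnot(max_norm > 0)
  nrm <- sqrt(grad_sumsq(grads))
  if (nrm > max_norm) grad_scale(grads, max_norm / nrm) else grads
}

# SGD step: model parameters minus lr * grads (grads are of the NLL).
apply_update <- function(model, grads, lr) {
  upd <- function(p, g) {
    for (nm in names(g)) if (is.numeric(g[[nm]]) && nm %in% names(p)) {
      p[[nm]] <- p[[nm]] - lr * g[[nm]]
    }
    p
  }
  if (!is.null(grads$crf)) {
    if (model$crf$parameterization == "pairvec") {
      model$crf$theta <- model$crf$theta - lr * grads$crf$theta
    } else {
      model$crf$W <- model$crf$W - lr * grads$crf$W
      model$crf$A <- model$crf$A - lr * grads$crf$A
    }
  }
  for (nm in c("tok_fwd", "tok_bwd", "char_fwd", "char_bwd", "cnn")) {
    if (!is.null(grads[[nm]])) model[[nm]] <- upd(model[[nm]], grads[[nm]])
  }
  if (!is.null(grads$token_emb)) {
    g <- rowsum(grads$token_emb$G, grads$token_emb$idx)
    rows <- as.integer(rownames(g))
    model$token_table$vectors[rows, ] <-
      model$token_table$vectors[rows, , drop = FALSE] - lr * g
  }
  if (!is.null(grads$char_emb)) {
    g <- rowsum(grads$char_emb$G, grads$char_emb$idx)
    rows <- as.integer(rownames(g))
    model$char_table$vectors[rows, ] <-
      model$char_table$vectors[rows, , drop = FALSE] - lr * g
  }
  model
}
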