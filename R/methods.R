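#' Tidy the training trace of a fitted recognizer
#'
#' @param x A trained `ner_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `mean_nll`, and
#'   `dev_exact_f1` when a dev corpus was supplied.
#' @export
tidy.ner_model <- function(x, ...) {
  log <- x$epoch_log
  if (all(is.na(log$dev_exact_f1))) log$dev_exact_f1 <- NULL
  log
}

#' One-row summary of a fitted recognizer
#'
#' @param x A trained `ner_model`.
#' @param ... Unused.
#' @return Tibble with `mode`, `n_labels`, `n_types`, `vocab_size`,
#'   `input_width`, `n_parameters`, `epochs`, `final_nll`.
#' @export
glance.ner_model <- function(x, ...) {
  count <- function(p) if (is.numeric(p)) length(p) else
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else 0
  n_par <- count(x$crf[c("theta", "W", "A")]) +
    sum(vapply(c("tok_fwd", "tok_bwd", "char_fwd", "char_bwd", "cnn"),
               function(nm) if (is.null(x[[nm]])) 0 else
                 count(x[[nm]][c("Wx", "Wh", "p_i", "p_f", "p_o", "b", "W")]),
               numeric(1))) +
    length(x$token_table$vectors) + length(x$char_table$vectors)
  tibble::tibble(
    mode = x$mode,
    n_labels = length(x$labels),
    n_types = length(x$types),
    vocab_size = length(x$token_table$index) - 2L,
    input_width = input_width(x),
    n_parameters = n_par,
    epochs = nrow(x$epoch_log),
    final_nll = if (nrow(x$epoch_log)) x$epoch_log$mean_nll[nrow(x$epoch_log)]
                else NA_real_
  )
}

#' Plot the training loss trace
#'
#' @param object A trained `ner_model`.
#' @param ... Unused.
#' @return A ggplot object: mean negative log-likelihood per epoch (and dev
#'   exact-F1 when present).
#' @export
autoplot.ner_model <- function(object, ...) {
  log <- object$epoch_log
  p <- ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$mean_nll)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean NLL per sentence") +
    ggplot2::theme_minimal()
  p
}
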