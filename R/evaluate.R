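# Micro-averaged precision/recall/F1 under five matching criteria:
#   exact   same boundary and same type
#   inexact character-span overlap and same type
#   span    character-span overlap (type ignored)
#   type    character-span overlap and same type (the span/type pair of
#           criteria used for event detection; operationally identical to
#           inexact, reported separately because tasks headline them
#           differently)
#   token   exact matching at token level: (document, token span, type)
#           triples covered by gold vs by prediction, compared as sets
#
# Overlap criteria use greedy one-to-one matching: candidate pairs sorted by
# decreasing overlap length, ties by earlier gold start then earlier pred
# start; each gold and each prediction matches at most once. This prevents a
# single prediction from matching many gold mentions.

eval_criteria <- c("exact", "inexact", "span", "type", "token")

f_score <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

mention_key <- function(m) {
  paste(m[["doc_id"]] %||% rep("doc", nrow(m)), m$type, m$start, m$end, sep = "\r")
}

#' Count matches between gold and predicted mentions
#'
#' @param gold,pred Mention tibbles with `type`, `start`, `end` (and
#'   `doc_id`; a single shared document is assumed when absent).
#' @param criterion One of `"exact"`, `"inexact"`, `"span"`, `"type"`,
#'   `"token"`.
#' @param tokens Tokens tibble (`doc_id`, `token`, `start`, `end`) from the
#'   shared tokenization; required by the `"token"` criterion only.
#' @return Named integer vector `c(tp, fp, fn)`.
#' @export
match_mentions <- function(gold, pred, criterion, tokens = NULL) {
  if (!criterion %in% eval_criteria) {
    abort_nerlstm(sprintf("unknown criterion '%s'", criterion),
                  "nerlstm_value_error")
  }
  if (criterion == "token") {
    if (is.null(tokens)) {
      abort_nerlstm("the token criterion needs the shared tokenization",
                    "nerlstm_value_error")
    }
    g <- token_triples(gold, tokens)
    p <- token_triples(pred, tokens)
    tp <- length(intersect(g, p))
    return(c(tp = tp, fp = length(p) - tp, fn = length(g) - tp))
  }
  if (criterion == "exact") {
    tp <- length(intersect(mention_key(gold), mention_key(pred)))
    return(c(tp = tp, fp = nrow(pred) - tp, fn = nrow(gold) - tp))
  }
  # overlap-based: inexact/type require equal type, span ignores it
  need_type <- criterion %in% c("inexact", "type")
  ng <- nrow(gold); np <- nrow(pred)
  if (ng == 0L || np == 0L) return(c(tp = 0L, fp = np, fn = ng))
  gdoc <- gold[["doc_id"]] %||% rep("doc", ng)
  pdoc <- pred[["doc_id"]] %||% rep("doc", np)
  cand <- list()
  for (i in seq_len(ng)) for (j in seq_len(np)) {
    if (gdoc[i] != pdoc[j]) next
    if (need_type && gold$type[i] != pred$type[j]) next
    ov <- min(gold$end[i], pred$end[j]) - max(gold$start[i], pred$start[j])
    if (ov > 0) cand[[length(cand) + 1L]] <- c(i, j, ov)
  }
  if (length(cand) == 0L) return(c(tp = 0L, fp = np, fn = ng))
  cand <- do.call(rbind, cand)
  ord <- order(-cand[, 3], gold$start[cand[, 1]], pred$start[cand[, 2]])
  used_g <- logical(ng); used_p <- logical(np); tp <- 0L
  for (r in ord) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_g[i] && !used_p[j]) {
      used_g[i] <- TRUE; used_p[j] <- TRUE; tp <- tp + 1L
    }
  }
  c(tp = tp, fp = np - tp, fn = ng - tp)
}

# (document, token span, type) triples covered by a mention set
token_triples <- function(mentions, tokens) {
  if (nrow(mentions) == 0L) return(character(0))
  tdoc <- tokens[["doc_id"]] %||% rep("doc", nrow(tokens))
  mdoc <- mentions[["doc_id"]] %||% rep("doc", nrow(mentions))
  out <- character(0)
  for (i in seq_len(nrow(mentions))) {
    hit <- tdoc == mdoc[i] & tokens$start < mentions$end[i] &
      tokens$end > mentions$start[i]
    if (any(hit)) {
      out <- c(out, paste(mdoc[i], tokens$start[hit], tokens$end[hit],
                          mentions$type[i], sep = "\r"))
    }
  }
  unique(out)
}

#' Micro-averaged precision, recall and F1
#'
#' Counts are summed over documents/types before the ratios are taken
#' (micro averaging). Zero denominators give 0 by convention.
#'
#' @param counts A tibble/data frame with columns `tp`, `fp`, `fn`, or a
#'   list of `c(tp, fp, fn)` vectors.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
micro_average <- function(counts) {
  if (is.data.frame(counts)) {
    tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  } else {
    m <- do.call(rbind, counts)
    tp <- sum(m[, "tp"]); fp <- sum(m[, "fp"]); fn <- sum(m[, "fn"])
  }
  s <- f_score(tp, fp, fn)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = unname(s["precision"]),
                 recall = unname(s["recall"]), f1 = unname(s["f1"]))
}

#' Evaluate predicted mentions against gold
#'
#' Computes overall micro-averaged results per criterion plus a per-entity-
#' type breakdown under each criterion's matching (for `"span"`, which
#' ignores types in matching, the breakdown partitions pairs by gold type
#' and counts unmatched predictions under their own type).
#'
#' @param gold,pred Mention tibbles (`doc_id`, `type`, `start`, `end`).
#' @param criteria Criteria to evaluate (default: all five).
#' @param tokens Shared tokenization (needed for `"token"`).
#' @param per_type Also emit per-type rows.
#' @return Tibble with columns `criterion`, `type` (`"<all>"` for overall),
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_corpus <- function(gold, pred, criteria = eval_criteria,
                            tokens = NULL, per_type = TRUE) {
  gdocs <- unique(gold[["doc_id"]] %||% "doc")
  pdocs <- unique(pred[["doc_id"]] %||% "doc")
  extra <- setdiff(pdocs, gdocs)
  if (length(extra) > 0L && nrow(pred) > 0L) {
    abort_nerlstm(sprintf("predictions for unknown document(s): %s",
                          paste(extra, collapse = ", ")),
                  "nerlstm_value_error")
  }
  types <- sort(unique(c(gold$type, pred$type)))
  rows <- list()
  for (cr in criteria) {
    cnt <- match_mentions(gold, pred, cr, tokens = tokens)
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble::tibble(criterion = cr, type = "<all>"),
                       micro_average(list(cnt)))
    if (per_type) {
      for (ty in types) {
        cnt <- match_mentions(gold[gold$type == ty, , drop = FALSE],
                              pred[pred$type == ty, , drop = FALSE],
                              cr, tokens = tokens)
        rows[[length(rows) + 1L]] <-
          dplyr::bind_cols(tibble::tibble(criterion = cr, type = ty),
                           micro_average(list(cnt)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nerlstm_eval", class(out))
  out
}

#' Plot an evaluation table
#'
#' Bar chart of precision/recall/F1 per criterion (overall rows only).
#'
#' @param object Output of [evaluate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nerlstm_eval <- function(object, ...) {
  plot_evaluation(object)
}

#' @rdname autoplot.nerlstm_eval
#' @param results Output of [evaluate_corpus()].
#' @export
plot_evaluation <- function(results) {
  df <- results[results$type == "<all>", ]
  long <- tidyr::pivot_longer(df, c("precision", "recall", "f1"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$criterion, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "matching criterion", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
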