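# SGD training loop, prediction, and the model archive.

# split a tagged tokens tibble into per-sentence lists
corpus_sentences <- function(corpus) {
  stopifnot(all(c("sentence", "token") %in% names(corpus)))
  doc <- corpus[["doc_id"]] %||% rep("doc", nrow(corpus))
  starts <- corpus[["start"]]; ends <- corpus[["end"]]; tags <- corpus[["tag"]]
  key <- paste(doc, corpus$sentence, sep = "\r")
  idx <- split(seq_len(nrow(corpus)), factor(key, levels = unique(key)))
  lapply(idx, function(i) {
    list(doc_id = doc[i[1]], sentence = corpus$sentence[i[1]],
         tokens = corpus$token[i],
         start = starts[i], end = ends[i], tags = tags[i])
  })
}

valid_tag_pattern <- "^(O|[BIES]-.+)$"

#' Train the recognizer with per-sentence SGD
#'
#' One sentence at a time (batch size 1): input layer with dropout, the
#' bidirectional LSTM encoder, CRF negative log-likelihood, backpropagation
#' through every parameter including both embedding tables, global-norm
#' gradient clipping, and a constant-step SGD update. Sentences are shuffled
#' every epoch under the config seed, so a fixed seed gives an identical
#' loss trace and identical final parameters.
#'
#' @param corpus Tagged tokens tibble with columns `doc_id`, `sentence`,
#'   `token`, `tag` (offsets optional; e.g. from [read_conll()] or
#'   [corpus_tokens()]).
#' @param mode Input representation: `"token"`, `"char-lstm"`, `"char-cnn"`
#'   or `"both"`.
#' @param config An [ner_config()].
#' @param embeddings Optional pre-trained token `embedding_table`.
#' @param dev Optional development corpus (same shape); when given, the
#'   checkpoint with the best exact-criterion F1 on it is returned and the
#'   per-epoch log gains a `dev_exact_f1` column.
#' @param quiet Suppress the per-epoch log line on stderr.
#' @return A trained `ner_model`; its `epoch_log` holds the training trace
#'   ([tidy()] returns it).
#' @export
ner_train <- function(corpus, mode = "token", config = ner_config(),
                      embeddings = NULL, dev = NULL, quiet = TRUE) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    abort_nerlstm("empty training corpus", "nerlstm_value_error")
  }
  if (!"tag" %in% names(corpus)) {
    abort_nerlstm("training corpus has no 'tag' column", "nerlstm_value_error")
  }
  bad <- !grepl(valid_tag_pattern, corpus$tag)
  if (any(bad)) {
    abort_nerlstm(sprintf("invalid tag(s): %s",
                          paste(utils::head(unique(corpus$tag[bad]), 5),
                                collapse = ", ")),
                  "nerlstm_value_error")
  }
  types <- sort(unique(sub("^[BIES]-", "", corpus$tag[corpus$tag != "O"])))
  if (length(types) == 0L) {
    abort_nerlstm("training corpus contains no entity tags",
                  "nerlstm_value_error")
  }
  vocab <- unique(corpus$token)
  alphabet <- sort(unique(strsplit(paste(vocab, collapse = ""), "")[[1]]))
  model <- ner_model(types, vocab, alphabet, mode = mode, config = config,
                     embeddings = embeddings)
  sents <- corpus_sentences(corpus)
  dev_sents <- if (!is.null(dev)) corpus_sentences(dev)

  old <- save_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_seed(config$seed, 100))
  best_f1 <- -Inf; best_model <- NULL
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(length(sents)) else seq_along(sents)
    total_nll <- 0
    for (s in sents[ord]) {
      sg <- sentence_grads(model, s$tokens, s$tags, training = TRUE)
      total_nll <- total_nll + sg$nll
      grads <- clip_gradients(sg$grads, config$clip)
      if (config$learning_rate > 0) {
        model <- apply_update(model, grads, config$learning_rate)
      }
    }
    mean_nll <- total_nll / length(sents)
    dev_f1 <- NA_real_
    if (!is.null(dev_sents)) {
      dev_f1 <- dev_exact_f1(model, dev_sents)
      if (dev_f1 > best_f1) { best_f1 <- dev_f1; best_model <- model }
    }
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch, mean_nll = mean_nll,
                                        dev_exact_f1 = dev_f1)
    if (!quiet) {
      message(sprintf("epoch %d  mean_nll %.4f%s", epoch, mean_nll,
                      if (is.na(dev_f1)) "" else sprintf("  dev_exact_f1 %.4f",
                                                         dev_f1)))
    }
  }
  log <- dplyr::bind_rows(log_rows)
  if (!is.null(best_model)) model <- best_model
  model$epoch_log <- log
  model
}

# exact-criterion F1 against the gold tags of pre-split sentences
dev_exact_f1 <- function(model, sents) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in sents) {
    tok <- tibble::tibble(token = s$tokens,
                          start = s$start %||% seq_along(s$tokens) - 1L,
                          end = s$end %||% seq_along(s$tokens))
    gold <- decode_bioes(tok, s$tags)
    pred <- decode_bioes(tok, predict_tags(model, s$tokens))
    cnt <- match_mentions(gold, pred, "exact")
    tp <- tp + cnt[["tp"]]; fp <- fp + cnt[["fp"]]; fn <- fn + cnt[["fn"]]
  }
  unname(f_score(tp, fp, fn)["f1"])
}

# Viterbi tags for one sentence (no dropout at inference)
predict_tags <- function(model, tokens) {
  X <- build_word_inputs(model, tokens)
  ctx <- run_bilstm(model$tok_fwd, model$tok_bwd, X)$context
  viterbi_decode(model$crf, ctx)$tags
}

#' Predict entity mentions
#'
#' Runs the full inference path: sentence split, tokenization, input layer
#' (no dropout), bidirectional LSTM, Viterbi decoding, BIOES decoding with
#' repair. Deterministic: identical input gives identical output.
#'
#' @param object A trained `ner_model`.
#' @param newdata Either a character vector of raw document texts (names
#'   used as `doc_id`s) or a tokens tibble with `doc_id`, `sentence`,
#'   `token`, `start`, `end`.
#' @param ... Unused.
#' @return A mentions tibble: `doc_id`, `type`, `start`, `end`, `text` with
#'   character spans into the raw documents.
#' @export
predict.ner_model <- function(object, newdata, ...) {
  raw_docs <- NULL
  if (is.character(newdata)) {
    ids <- names(newdata) %||% paste0("doc", seq_along(newdata))
    raw_docs <- stats::setNames(newdata, ids)
    tok <- purrr::map_dfr(seq_along(newdata), function(i) {
      tokenize_document(newdata[i], doc_id = ids[i])
    })
  } else {
    tok <- newdata
  }
  empty <- tibble::tibble(doc_id = character(), type = character(),
                          start = integer(), end = integer(),
                          text = character())
  if (is.null(tok) || nrow(tok) == 0L) return(empty)
  sents <- corpus_sentences(tok)
  out <- purrr::map_dfr(sents, function(s) {
    tags <- predict_tags(object, s$tokens)
    tokens <- tibble::tibble(token = s$tokens, start = s$start, end = s$end)
    m <- decode_bioes(tokens, tags)
    if (nrow(m) == 0L) return(NULL)
    if (!is.null(raw_docs)) {  # surface from the raw document, not token glue
      m$text <- substring(raw_docs[[s$doc_id]], m$start + 1L, m$end)
    }
    tibble::tibble(doc_id = s$doc_id, m)
  })
  if (nrow(out) == 0L) empty else out
}

#' Tag a tokens tibble with BIOES labels
#'
#' Lower-level companion to [predict.ner_model()]: returns the Viterbi tag
#' per token instead of decoded mentions (the shape [write_conll()] takes).
#'
#' @param model A trained `ner_model`.
#' @param tokens Tokens tibble with `doc_id`, `sentence`, `token`.
#' @return The input tibble with a `tag` column.
#' @export
tag_corpus <- function(model, tokens) {
  sents <- corpus_sentences(tokens)
  tokens$tag <- unlist(lapply(sents, function(s) predict_tags(model, s$tokens)),
                       use.names = FALSE)
  tokens
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a model archive
#'
#' The archive is a single self-describing file holding every parameter,
#' both embedding tables, the label set and the config snapshot, plus a
#' format version. A loaded model produces bit-identical predictions.
#'
#' @param model A `ner_model`.
#' @param path Archive file path.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "nerlstm_model", version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort_nerlstm(sprintf("no such model archive: %s", path),
                  "nerlstm_io_error")
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort_nerlstm(sprintf("corrupt model archive: %s", path),
                  "nerlstm_io_error")
  })
  if (!is.list(obj) || !identical(obj$format, "nerlstm_model")) {
    abort_nerlstm(sprintf("not a model archive: %s", path),
                  "nerlstm_io_error")
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    abort_nerlstm(sprintf("archive version %s, expected %d",
                          format(obj$version), MODEL_FORMAT_VERSION),
                  "nerlstm_io_error")
  }
  obj$model
}
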