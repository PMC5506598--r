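#' @keywords internal
new_embedding_table <- function(symbols, vectors, unk = "<unk>", pad = "<pad>") {
  stopifnot(is.matrix(vectors), nrow(vectors) == length(symbols) + 2L)
  rows <- c(symbols, unk, pad)
  structure(list(
    index = stats::setNames(seq_along(rows), rows),
    vectors = vectors,
    dim = ncol(vectors),
    unk_index = length(symbols) + 1L,
    pad_index = length(symbols) + 2L
  ), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d symbols (+unk,+pad), dim %d>\n",
              length(x$index) - 2L, x$dim))
  invisible(x)
}

#' Load token embeddings from word2vec text format
#'
#' Accepts the plain-text word2vec format: an optional header line
#' `count dim`, then one `word v1 ... vd` line per entry. Two reserved rows
#' are appended: UNK (the mean of all loaded vectors, so unknown words sit at
#' the centre of the embedding cloud) and PAD (zeros).
#'
#' @param path File path.
#' @param expected_dim If given, a dimension mismatch is an error.
#' @return An `embedding_table`.
#' @export
load_word2vec_text <- function(path, expected_dim = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(sub("[[:space:]]+$", "", lines))]
  if (length(lines) == 0L) abort_nerlstm(sprintf("%s: empty file", path),
                                         "nerlstm_parse_error")
  first <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  start_line <- if (has_header) 2L else 1L
  if (has_header && length(lines) < 2L) {
    abort_nerlstm(sprintf("%s: header only, no vectors", path),
                  "nerlstm_parse_error")
  }
  words <- character(0); vecs <- list(); d <- NULL
  for (i in start_line:length(lines)) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) < 2L) {
      abort_nerlstm(sprintf("%s:%d: malformed line", path, i),
                    "nerlstm_parse_error")
    }
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) {
      abort_nerlstm(sprintf("%s:%d: non-numeric vector entry", path, i),
                    "nerlstm_parse_error")
    }
    if (is.null(d)) {
      d <- length(v)
      if (!is.null(expected_dim) && d != expected_dim) {
        abort_nerlstm(sprintf("%s:%d: dimension %d, expected %d",
                              path, i, d, expected_dim), "nerlstm_parse_error")
      }
    } else if (length(v) != d) {
      abort_nerlstm(sprintf("%s:%d: dimension %d, expected %d",
                            path, i, length(v), d), "nerlstm_parse_error")
    }
    words <- c(words, parts[1])
    vecs[[length(vecs) + 1L]] <- v
  }
  mat <- do.call(rbind, vecs)
  unk <- colMeans(mat)
  new_embedding_table(words, rbind(mat, unk, rep(0, d)))
}

#' Write an embedding table in word2vec text format
#'
#' Only the real vocabulary rows are written (UNK/PAD are reconstructed on
#' load). Values are printed with 17 significant digits so a load/write/load
#' round-trip preserves them.
#'
#' @param table An `embedding_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word2vec_text <- function(table, path) {
  words <- names(table$index)[seq_len(length(table$index) - 2L)]
  n <- length(words)
  lines <- c(sprintf("%d %d", n, table$dim),
             vapply(seq_len(n), function(i) {
               paste(c(words[i], format(table$vectors[i, ], digits = 17)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Randomly initialized embedding table
#'
#' Entries are drawn i.i.d. uniform in `[low, high]` under the given seed
#' (the convention used for character embeddings, range `[-1, 1]`). The PAD
#' row is zero; the UNK row is drawn like any other.
#'
#' @param symbols Character vector of vocabulary symbols (words or single
#'   characters). Must be non-empty and duplicate-free.
#' @param dim Embedding dimension (>= 1).
#' @param seed Integer seed; the same seed yields an identical table.
#' @param low,high Uniform range bounds.
#' @return An `embedding_table`.
#' @export
init_random_table <- function(symbols, dim, seed, low = -1, high = 1) {
  if (length(symbols) == 0L) {
    abort_nerlstm("empty vocabulary", "nerlstm_value_error")
  }
  if (anyDuplicated(symbols)) {
    abort_nerlstm("duplicate symbols in vocabulary", "nerlstm_value_error")
  }
  if (!is.numeric(dim) || dim < 1) {
    abort_nerlstm("dim must be >= 1", "nerlstm_value_error")
  }
  old <- save_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(symbols) + 1L  # + UNK
  mat <- matrix(stats::runif(n * dim, low, high), nrow = n, ncol = dim)
  new_embedding_table(symbols, rbind(mat, rep(0, dim)))
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Look up indices for a token sequence
#'
#' Back-off policy: exact match, then (if `lowercase` is `TRUE`) lowercased
#' match, then UNK. Exposed because training must know which rows were used
#' in order to fine-tune exactly those rows.
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector of token surfaces.
#' @param lowercase Apply the lowercase back-off (default `TRUE`).
#' @return Integer vector of row indices.
#' @export
lookup_indices <- function(table, tokens, lowercase = TRUE) {
  idx <- unname(table$index[tokens])
  if (lowercase) {
    miss <- is.na(idx)
    if (any(miss)) idx[miss] <- unname(table$index[tolower(tokens[miss])])
  }
  idx[is.na(idx)] <- table$unk_index
  idx
}

#' Embed a token sequence
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector (or a tokens tibble with a `token` column).
#' @param lowercase Apply the lowercase back-off (default `TRUE`).
#' @return Numeric matrix, one row per token, `table$dim` columns.
#' @export
lookup_sequence <- function(table, tokens, lowercase = TRUE) {
  if (is.data.frame(tokens)) tokens <- tokens$token
  table$vectors[lookup_indices(table, tokens, lowercase), , drop = FALSE]
}
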