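#' Read a CoNLL-style token-per-line file
#'
#' Dialect: UTF-8, one `surface tag` pair per line separated by blanks, an
#' empty line between sentences. Trailing whitespace and a missing final blank
#' line are tolerated. Character offsets are synthesized by joining tokens of
#' a sentence with single spaces (the format does not carry offsets).
#'
#' @param path File path.
#' @param doc_id Document id assigned to the whole file.
#' @return Tibble with columns `doc_id`, `sentence`, `token`, `start`, `end`,
#'   `tag`.
#' @export
read_conll <- function(path, doc_id = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list(); sent <- 1L; pos <- 0L; any_tok <- FALSE
  for (i in seq_along(lines)) {
    line <- sub("[[:space:]]+$", "", lines[i])
    if (!nzchar(line)) {
      if (any_tok) { sent <- sent + 1L; pos <- 0L; any_tok <- FALSE }
      next
    }
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(parts) != 2L) {
      abort_nerlstm(sprintf("%s:%d: expected 'surface tag', got %d column(s)",
                            path, i, length(parts)), "nerlstm_parse_error")
    }
    if (any_tok) pos <- pos + 1L  # single space between tokens
    rows[[length(rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id, sentence = sent, token = parts[1],
      start = pos, end = pos + nchar(parts[1]), tag = parts[2])
    pos <- pos + nchar(parts[1])
    any_tok <- TRUE
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(doc_id = character(), sentence = integer(),
                          token = character(), start = integer(),
                          end = integer(), tag = character()))
  }
  dplyr::bind_rows(rows)
}

#' Write a tagged corpus in CoNLL format
#'
#' @param corpus Tibble with at least `sentence`, `token`, `tag` (and
#'   optionally `doc_id`; document breaks are rendered as sentence breaks).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  stopifnot(all(c("sentence", "token", "tag") %in% names(corpus)))
  key <- paste(corpus[["doc_id"]] %||% "doc", corpus$sentence)
  out <- character(0)
  for (k in unique(key)) {
    s <- corpus[key == k, ]
    out <- c(out, paste(s$token, s$tag), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read a document with standoff entity annotations
#'
#' Standoff dialect: one mention per line, `type<TAB>start<TAB>end<TAB>surface`
#' with 0-based half-open character spans against the raw document.
#'
#' @param text_path Path to the raw UTF-8 document.
#' @param ann_path Path to the annotation TSV.
#' @param doc_id Document id for the returned mentions.
#' @return List with `text` (document string) and `mentions` (tibble with
#'   `doc_id`, `type`, `start`, `end`, `text`).
#' @export
read_standoff <- function(text_path, ann_path, doc_id = basename(text_path)) {
  text <- paste(readLines(text_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  lines <- readLines(ann_path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(sub("[[:space:]]+$", "", lines))
  lines <- lines[keep]; lineno <- which(keep)
  if (length(lines) == 0L) {
    return(list(text = text, mentions = tibble::tibble(
      doc_id = character(), type = character(), start = integer(),
      end = integer(), text = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad) > 0L) {
    abort_nerlstm(sprintf("%s:%d: expected 4 tab-separated fields",
                          ann_path, lineno[bad[1]]), "nerlstm_parse_error")
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort_nerlstm(sprintf("%s:%d: non-integer span", ann_path, lineno[bad]),
                  "nerlstm_parse_error")
  }
  list(text = text, mentions = tibble::tibble(
    doc_id = doc_id, type = m[, 1], start = start, end = end, text = m[, 4]))
}

#' Write standoff annotations
#'
#' @param mentions Tibble with `type`, `start`, `end`, `text`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_standoff <- function(mentions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", mentions$type, mentions$start,
                   mentions$end, mentions$text)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
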