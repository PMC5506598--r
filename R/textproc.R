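#' Split a document into sentences
#'
#' Applies the two-rule splitter used throughout the package: a sentence ends
#' at a newline, `.`, `?` or `!`. The punctuation delimiters are kept as part
#' of the sentence text; newlines and surrounding blanks are trimmed. Empty
#' fragments are dropped. No abbreviation handling is attempted: a period
#' always terminates a sentence, so "Dr. Smith" yields two sentences. This is
#' deliberate — the downstream tagger is robust to over-splitting, and the
#' rule is exactly reproducible.
#'
#' @param text A single document string (may be empty).
#' @return A tibble with columns `text` (sentence string) and `start`
#'   (0-based character offset of the sentence into `text`). Zero rows for
#'   an empty or all-whitespace document.
#' @examples
#' split_sentences("No pain. Afebrile")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(text = character(), start = integer())
  if (is.na(text) || !nzchar(text)) return(empty)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  term <- chars %in% c(".", "?", "!", "\n")
  # raw fragment = run of characters up to and including a terminator
  ends <- which(term)
  if (length(ends) == 0L || ends[length(ends)] != length(chars)) {
    ends <- c(ends, length(chars))
  }
  starts <- c(1L, ends[-length(ends)] + 1L)

  out_text <- character(0)
  out_start <- integer(0)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    frag <- substr(text, s, e)
    # trim whitespace (incl. the newline terminator) from both ends,
    # keeping offsets anchored to the raw document
    lead <- nchar(frag) - nchar(sub("^[[:space:]]+", "", frag))
    frag <- sub("^[[:space:]]+", "", frag)
    frag <- sub("[[:space:]]+$", "", frag)
    if (nzchar(frag)) {
      out_text <- c(out_text, frag)
      out_start <- c(out_start, s - 1L + lead)  # 0-based
    }
  }
  tibble::tibble(text = out_text, start = out_start)
}

# one token per maximal run of a single character class: letters, digits, other
.token_pattern <- "\\p{L}+|\\p{N}+|[^\\p{L}\\p{N}\\s]+"

#' Tokenize a sentence into character-class runs
#'
#' Splits on blank characters first, then re-splits every chunk into maximal
#' runs of a single character class (letters, digits, other), so that e.g.
#' `"4/16/91CPT Code:"` becomes `4 / 16 / 91 CPT Code :`. Offsets are 0-based,
#' half-open, and anchored into the source document via `offset`.
#'
#' @param text Sentence text (non-empty string).
#' @param offset 0-based character offset of `text` within its source
#'   document; added to all token offsets.
#' @return A tibble with columns `token`, `start`, `end` where
#'   `substr(doc, start + 1, end)` recovers the token.
#' @examples
#' tokenize("4/16/91CPT Code:")
#' @export
tokenize <- function(text, offset = 0L) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1L),
    start = as.integer(m - 1L + offset),
    end   = as.integer(m - 1L + len + offset)
  )
}

#' Tokenize a whole document
#'
#' Convenience wrapper: [split_sentences()] then [tokenize()] per sentence.
#'
#' @param text Document string.
#' @param doc_id Document identifier carried into the output.
#' @return A tibble with columns `doc_id`, `sentence` (1-based sentence
#'   index), `token`, `start`, `end`; offsets are document-level.
#' @export
tokenize_document <- function(text, doc_id = "doc") {
  sents <- split_sentences(text)
  if (nrow(sents) == 0L) {
    return(tibble::tibble(doc_id = character(), sentence = integer(),
                          token = character(), start = integer(), end = integer()))
  }
  purrr::map_dfr(seq_len(nrow(sents)), function(i) {
    tok <- tokenize(sents$text[i], offset = sents$start[i])
    if (nrow(tok) == 0L) return(NULL)
    tibble::tibble(doc_id = doc_id, sentence = i, tok)
  })
}
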