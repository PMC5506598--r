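#' Encode mentions of one sentence as a BIOES tag sequence
#'
#' A multi-token mention of type `t` becomes `B-t (I-t)* E-t`, a single-token
#' mention becomes `S-t`, all other tokens `O`. Mentions must align exactly
#' with token boundaries and must not overlap; violations are errors that name
#' the offending mention (model output never reaches this function — gold
#' annotations do, and silent misalignment would corrupt training data).
#'
#' @param tokens Tibble with columns `token`, `start`, `end` for one sentence
#'   (document-level, 0-based half-open offsets).
#' @param mentions Tibble with columns `type`, `start`, `end` for mentions
#'   lying inside this sentence. Zero rows allowed.
#' @return Character vector of BIOES tags, one per token.
#' @export
encode_bioes <- function(tokens, mentions) {
  n <- nrow(tokens)
  tags <- rep("O", n)
  if (is.null(mentions) || nrow(mentions) == 0L) return(tags)
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  prev_end <- -1L
  for (i in seq_len(nrow(mentions))) {
    m <- mentions[i, ]
    if (m$start < prev_end) {
      abort_nerlstm(sprintf(
        "overlapping mention: type=%s span=[%d,%d) overlaps a previous mention",
        m$type, m$start, m$end), "nerlstm_encode_error")
    }
    first <- which(tokens$start == m$start)
    last <- which(tokens$end == m$end)
    if (length(first) != 1L || length(last) != 1L || last < first) {
      abort_nerlstm(sprintf(
        "mention not aligned with token boundaries: type=%s span=[%d,%d)",
        m$type, m$start, m$end), "nerlstm_encode_error")
    }
    if (any(tags[first:last] != "O")) {
      abort_nerlstm(sprintf(
        "overlapping mention: type=%s span=[%d,%d)", m$type, m$start, m$end),
        "nerlstm_encode_error")
    }
    if (first == last) {
      tags[first] <- paste0("S-", m$type)
    } else {
      tags[first] <- paste0("B-", m$type)
      tags[last] <- paste0("E-", m$type)
      if (last > first + 1L) tags[(first + 1L):(last - 1L)] <- paste0("I-", m$type)
    }
    prev_end <- m$end
  }
  tags
}

#' Decode a BIOES tag sequence into entity mentions
#'
#' Inverse of [encode_bioes()] on valid input, with a deterministic repair
#' policy for the invalid sequences a model can emit: scanning left to right,
#' a mention opens at `B-t` or at an orphan `I-t`/`E-t`; it closes at `E-t`,
#' before an `S`, an `O`, a type change or a new `B`, and at sentence end.
#' Predicted entity evidence is therefore never discarded.
#'
#' @param tokens Tibble with `token`, `start`, `end` for one sentence.
#' @param tags Character vector of BIOES tags, same length.
#' @return Tibble of mentions with columns `type`, `start`, `end`, `text`
#'   (character spans from token offsets; `text` is the space-joined surface).
#' @export
decode_bioes <- function(tokens, tags) {
  n <- nrow(tokens)
  stopifnot(length(tags) == n)
  out_type <- character(0); out_first <- integer(0); out_last <- integer(0)
  open_type <- NULL; open_first <- NA_integer_

  close_open <- function(last) {
    out_type <<- c(out_type, open_type)
    out_first <<- c(out_first, open_first)
    out_last <<- c(out_last, last)
    open_type <<- NULL
  }

  for (t in seq_len(n)) {
    tag <- tags[t]
    if (tag == "O") {
      if (!is.null(open_type)) close_open(t - 1L)
      next
    }
    kind <- substr(tag, 1, 1)
    type <- substring(tag, 3)
    if (kind == "S") {
      if (!is.null(open_type)) close_open(t - 1L)
      out_type <- c(out_type, type); out_first <- c(out_first, t); out_last <- c(out_last, t)
    } else if (kind == "B") {
      if (!is.null(open_type)) close_open(t - 1L)
      open_type <- type; open_first <- t
    } else {  # I or E (possibly orphans)
      if (!is.null(open_type) && open_type != type) close_open(t - 1L)
      if (is.null(open_type)) { open_type <- type; open_first <- t }
      if (kind == "E") close_open(t)
    }
  }
  if (!is.null(open_type)) close_open(n)

  if (length(out_type) == 0L) {
    return(tibble::tibble(type = character(), start = integer(),
                          end = integer(), text = character()))
  }
  tibble::tibble(
    type = out_type,
    start = tokens$start[out_first],
    end = tokens$end[out_last],
    text = vapply(seq_along(out_type), function(i) {
      paste(tokens$token[out_first[i]:out_last[i]], collapse = " ")
    }, character(1))
  )
}

#' Check BIOES transition validity of a tag sequence
#'
#' `I-t` and `E-t` may only follow `B-t` or `I-t` of the same type; a `B-t`
#' must eventually be closed by an `E-t`; `S-t` and `O` stand alone.
#'
#' @param tags Character vector of BIOES tags.
#' @return `TRUE` if the sequence is structurally valid, else `FALSE`.
#' @export
is_valid_bioes <- function(tags) {
  open <- NULL
  for (tag in tags) {
    if (tag == "O") { if (!is.null(open)) return(FALSE); next }
    kind <- substr(tag, 1, 1); type <- substring(tag, 3)
    if (kind == "B") { if (!is.null(open)) return(FALSE); open <- type }
    else if (kind == "S") { if (!is.null(open)) return(FALSE) }
    else if (kind == "I") { if (is.null(open) || open != type) return(FALSE) }
    else if (kind == "E") { if (is.null(open) || open != type) return(FALSE); open <- NULL }
    else return(FALSE)
  }
  is.null(open)
}

#' Full BIOES label inventory for a set of entity types
#'
#' @param types Character vector of entity type names.
#' @return Character vector: `O` plus `B-/I-/E-/S-` labels per type.
#' @export
bioes_labels <- function(types) {
  c("O", as.vector(outer(c("B-", "I-", "E-", "S-"), types, paste0)))
}
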