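# Seeded generator of clinical-style annotated corpora.
#
# Documents are short sentences of nonsense carrier words with typed entity
# mentions embedded at random positions. Entity surfaces carry optional
# morphology cues — suffixed drug/disease-like words ("...itis", "...cillin")
# or digit patterns (dates "d/dd/dd", numeric IDs) — so that entity
# membership is predictable from surface shape alone, the property
# character-level word representations are meant to capture. Annotations
# align with the package tokenizer's boundaries by construction, and all
# randomness is governed by the spec seed.

default_cues <- list(
  problem = list(kind = "suffix", value = "itis"),
  test = list(kind = "suffix", value = "ase"),
  treatment = list(kind = "suffix", value = "cillin"),
  date = list(kind = "digits", value = "date"),
  id = list(kind = "digits", value = "id")
)

#' Specification of a synthetic annotated corpus
#'
#' @param n_documents Number of training documents (the test split has
#'   `ceiling(n_documents * test_fraction)` additional, disjoint documents).
#' @param sentences_per_doc Length-2 integer range.
#' @param entity_types Entity type inventory. The five defaults come with
#'   morphology cues (suffixes for problem/test/treatment, digit patterns
#'   for date/id); other types default to their own name as suffix.
#' @param vocab_size Size of the closed carrier-word vocabulary.
#' @param lexicon_size Entity head words per suffixed type.
#' @param entity_density Expected entity mentions per sentence (Poisson,
#'   capped at 4).
#' @param multi_token_rate Fraction of suffixed-type mentions that get a
#'   modifier word (producing B/I/E tags rather than S).
#' @param oov_rate Fraction of suffixed-type entity head words in the *test*
#'   split that are freshly generated, hence unseen in training (1.0 makes
#'   every test entity head out-of-vocabulary).
#' @param morphology_cue Keep the surface cues (`TRUE`); with `FALSE`,
#'   entity heads are plain carrier-like words and type is unpredictable
#'   from morphology.
#' @param test_fraction Test documents as a fraction of `n_documents`.
#' @param seed Master seed; same spec + seed gives byte-identical corpora.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_documents = 20, sentences_per_doc = c(3L, 6L),
                        entity_types = c("problem", "test", "treatment",
                                         "date", "id"),
                        vocab_size = 80, lexicon_size = 25,
                        entity_density = 1.0, multi_token_rate = 0.3,
                        oov_rate = 0, morphology_cue = TRUE,
                        test_fraction = 0.5, seed = 1L) {
  if (entity_density < 0 || entity_density > 4) {
    abort_nerlstm("entity_density must be in [0, 4] (sentences are short)",
                  "nerlstm_value_error")
  }
  stopifnot(n_documents >= 1, vocab_size >= 10, lexicon_size >= 2,
            oov_rate >= 0, oov_rate <= 1,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1,
            sentences_per_doc[2] >= sentences_per_doc[1])
  structure(list(
    n_documents = n_documents,
    sentences_per_doc = as.integer(sentences_per_doc),
    entity_types = entity_types, vocab_size = vocab_size,
    lexicon_size = lexicon_size, entity_density = entity_density,
    multi_token_rate = multi_token_rate, oov_rate = oov_rate,
    morphology_cue = morphology_cue, test_fraction = test_fraction,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

cue_for <- function(type) {
  default_cues[[type]] %||% list(kind = "suffix", value = type)
}

syllable_word <- function(n_syll) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syll, TRUE), sample(vow, n_syll, TRUE)),
         collapse = "")
}

suffixes_in_use <- function(types) {
  vapply(types, function(ty) {
    cue <- cue_for(ty)
    if (cue$kind == "suffix") cue$value else ""
  }, character(1))
}

# carrier vocabulary: nonsense lowercase words, never ending in a cue suffix
gen_carrier_vocab <- function(spec) {
  sfx <- suffixes_in_use(spec$entity_types)
  sfx <- sfx[nzchar(sfx)]
  words <- character(0)
  while (length(words) < spec$vocab_size) {
    w <- syllable_word(sample(2:4, 1))
    if (any(vapply(sfx, function(s) endsWith(w, s), logical(1)))) next
    words <- unique(c(words, w))
  }
  words[seq_len(spec$vocab_size)]
}

gen_stem <- function(avoid = character(0)) {
  repeat {
    s <- syllable_word(sample(2:3, 1))
    if (!s %in% avoid) return(s)
  }
}

# entity surface for one mention; returns the space-joined chunk string
gen_entity_surface <- function(type, lexicon, modifiers, spec, oov,
                               train_stems) {
  cue <- cue_for(type)
  if (cue$kind == "digits") {
    if (cue$value == "date") {
      surf <- sprintf("%d/%d/%02d", sample(1:12, 1), sample(1:28, 1),
                      sample(0:99, 1))
    } else {
      surf <- paste0(sample(0:9, 6, TRUE), collapse = "")
    }
    return(surf)
  }
  head <- if (oov) {
    stem <- gen_stem(avoid = train_stems[[type]])
    if (spec$morphology_cue) paste0(stem, cue$value) else stem
  } else {
    sample(lexicon[[type]], 1)
  }
  if (stats::runif(1) < spec$multi_token_rate) {
    paste(sample(modifiers, 1), head)
  } else {
    head
  }
}

#' Generate a synthetic annotated corpus
#'
#' Returns disjoint train and test splits, each a list with a `docs` tibble
#' (`doc_id`, `text`) and a standoff `mentions` tibble (`doc_id`, `type`,
#' `start`, `end`, `text` with 0-based half-open character spans). Carrier
#' vocabulary and entity lexicons are drawn under sub-seeds derived
#' independently from the master seed, so changing e.g. `oov_rate` does not
#' reshuffle the carrier text.
#'
#' @param spec A [corpus_spec()].
#' @return List with `train`, `test` (each `docs` + `mentions`) and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  old <- save_rng_state(); on.exit(restore_rng_state(old))

  set.seed(derive_seed(spec$seed, 11))
  carriers <- gen_carrier_vocab(spec)

  set.seed(derive_seed(spec$seed, 12))
  modifiers <- c("acute", "chronic", "mild", "severe", "left", "right")
  train_stems <- list(); lexicon <- list()
  for (ty in spec$entity_types) {
    cue <- cue_for(ty)
    if (cue$kind == "suffix") {
      stems <- character(0)
      while (length(stems) < spec$lexicon_size) {
        stems <- unique(c(stems, gen_stem()))
      }
      stems <- stems[seq_len(spec$lexicon_size)]
      train_stems[[ty]] <- stems
      lexicon[[ty]] <- if (spec$morphology_cue) paste0(stems, cue$value) else stems
    }
  }

  n_test <- max(1L, ceiling(spec$n_documents * spec$test_fraction))
  make_split <- function(doc_ids, seed_offset, oov_rate) {
    docs <- vector("list", length(doc_ids))
    ments <- vector("list", length(doc_ids))
    for (di in seq_along(doc_ids)) {
      set.seed(derive_seed(spec$seed, seed_offset + di))
      lo <- spec$sentences_per_doc[1]; hi <- spec$sentences_per_doc[2]
      n_sent <- lo + sample.int(hi - lo + 1L, 1) - 1L  # safe when lo == hi
      text <- ""
      doc_m <- list()
      for (si in seq_len(n_sent)) {
        n_car <- sample(4:9, 1)
        words <- sample(carriers, n_car, TRUE)
        if (stats::runif(1) < 0.15) {  # occasional mid-sentence comma
          p <- sample(seq_len(n_car), 1)
          words[p] <- paste0(words[p], ",")
        }
        n_ent <- min(stats::rpois(1, spec$entity_density), 4L)
        chunks <- words
        ent_here <- list()
        if (n_ent > 0) {
          slots <- sort(sample(seq_len(n_car + 1L) - 1L, n_ent))
          for (e in rev(seq_len(n_ent))) {
            ty <- sample(spec$entity_types, 1)
            oov <- stats::runif(1) < oov_rate
            surf <- gen_entity_surface(ty, lexicon, modifiers, spec, oov,
                                       train_stems)
            chunks <- append(chunks, surf, after = slots[e])
            # entities at strictly smaller slots are inserted afterwards and
            # each shifts this chunk right by one: final index = slot + e
            ent_here[[length(ent_here) + 1L]] <-
              list(type = ty, pos = slots[e] + e, surf = surf)
          }
        }
        sent <- paste(chunks, collapse = " ")
        terminator <- sample(c(". ", ". ", "? ", "! ", "\n"), 1)
        base <- nchar(text)
        # character offsets of each chunk within the document
        off <- base + c(0L, cumsum(nchar(chunks) + 1L)[-length(chunks)])
        for (m in ent_here) {
          st <- off[m$pos]
          doc_m[[length(doc_m) + 1L]] <- tibble::tibble(
            doc_id = doc_ids[di], type = m$type, start = st,
            end = st + nchar(m$surf), text = m$surf)
        }
        text <- paste0(text, sent, terminator)
      }
      text <- sub("[[:space:]]+$", "", text)
      docs[[di]] <- tibble::tibble(doc_id = doc_ids[di], text = text)
      ments[[di]] <- if (length(doc_m)) dplyr::bind_rows(doc_m) else NULL
    }
    empty_m <- tibble::tibble(doc_id = character(), type = character(),
                              start = integer(), end = integer(),
                              text = character())
    list(docs = dplyr::bind_rows(docs),
         mentions = if (length(ments)) dplyr::bind_rows(ments) else empty_m)
  }

  train <- make_split(sprintf("train-%03d", seq_len(spec$n_documents)),
                      1000L, 0)
  test <- make_split(sprintf("test-%03d", seq_len(n_test)),
                     5000L, spec$oov_rate)
  list(train = train, test = test, spec = spec)
}

#' Tokenize and BIOES-tag a corpus split
#'
#' Runs the package tokenizer over every document of a split and encodes the
#' standoff mentions as BIOES tags — the tagged-tokens shape [ner_train()]
#' consumes. Mentions crossing sentence boundaries (none are generated, but
#' externally loaded data may have them) raise the encoding error.
#'
#' @param split A `list(docs, mentions)` as produced by [generate_corpus()].
#' @return Tagged tokens tibble: `doc_id`, `sentence`, `token`, `start`,
#'   `end`, `tag`.
#' @export
corpus_tokens <- function(split) {
  purrr::map_dfr(seq_len(nrow(split$docs)), function(i) {
    id <- split$docs$doc_id[i]
    tok <- tokenize_document(split$docs$text[i], doc_id = id)
    if (nrow(tok) == 0L) return(NULL)
    ments <- split$mentions[split$mentions$doc_id == id, , drop = FALSE]
    purrr::map_dfr(split(tok, tok$sentence), function(st) {
      inside <- ments[ments$start >= min(st$start) & ments$end <= max(st$end), ]
      st$tag <- encode_bioes(st, inside)
      st
    })
  })
}

#' Corpus summary counts
#'
#' @param split A `list(docs, mentions)` split.
#' @return One-row tibble: `documents`, `sentences`, `tokens`, `mentions`,
#'   plus one `mentions_<type>` column per entity type present.
#' @export
corpus_stats <- function(split) {
  if (nrow(split$docs) == 0L) {
    return(tibble::tibble(documents = 0L, sentences = 0L, tokens = 0L,
                          mentions = 0L))
  }
  tok <- purrr::map_dfr(seq_len(nrow(split$docs)), function(i) {
    tokenize_document(split$docs$text[i], doc_id = split$docs$doc_id[i])
  })
  out <- tibble::tibble(
    documents = nrow(split$docs),
    sentences = nrow(dplyr::distinct(tok, .data$doc_id, .data$sentence)),
    tokens = nrow(tok),
    mentions = nrow(split$mentions))
  if (nrow(split$mentions) > 0L) {
    per <- table(split$mentions$type)
    for (ty in names(per)) out[[paste0("mentions_", ty)]] <- as.integer(per[[ty]])
  }
  out
}

#' Write a corpus split to disk
#'
#' One `<doc_id>.txt` / `<doc_id>.ann` standoff pair per document plus a
#' single `corpus.conll` with the tokenized, BIOES-tagged form.
#'
#' @param split A `list(docs, mentions)` split.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(split$docs))) {
    id <- split$docs$doc_id[i]
    writeLines(split$docs$text[i], file.path(dir, paste0(id, ".txt")),
               useBytes = TRUE)
    write_standoff(split$mentions[split$mentions$doc_id == id, ],
                   file.path(dir, paste0(id, ".ann")))
  }
  write_conll(corpus_tokens(split), file.path(dir, "corpus.conll"))
  invisible(dir)
}
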