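test_that("matching criteria follow their boundary/type definitions", {
  g <- toy_mention("problem", 0, 10)

  same <- toy_mention("problem", 0, 10)
  for (cr in c("exact", "inexact", "span", "type")) {
    expect_equal(match_mentions(g, same, cr), c(tp = 1L, fp = 0L, fn = 0L))
  }

  shorter <- toy_mention("problem", 0, 5)
  expect_equal(match_mentions(g, shorter, "exact"), c(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(match_mentions(g, shorter, "inexact"), c(tp = 1L, fp = 0L, fn = 0L))

  wrong_type <- toy_mention("test", 0, 10)
  expect_equal(match_mentions(g, wrong_type, "exact"), c(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(match_mentions(g, wrong_type, "span"), c(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(match_mentions(g, wrong_type, "type"), c(tp = 0L, fp = 1L, fn = 1L))

  expect_error(match_mentions(g, same, "bogus"), class = "nerlstm_value_error")
})

test_that("overlap matching is one-to-one, preferring larger overlaps", {
  gold <- dplyr::bind_rows(toy_mention("problem", 0, 10),
                           toy_mention("problem", 12, 20))
  # one prediction overlapping both golds may only match once
  pred <- toy_mention("problem", 5, 15)
  cnt <- match_mentions(gold, pred, "inexact")
  expect_equal(cnt, c(tp = 1L, fp = 0L, fn = 1L))

  # the larger overlap wins the pairing
  pred2 <- dplyr::bind_rows(toy_mention("problem", 0, 9),   # 9 chars with g1
                            toy_mention("problem", 9, 11))  # 1 char with g1
  cnt2 <- match_mentions(toy_mention("problem", 0, 10), pred2, "inexact")
  expect_equal(cnt2, c(tp = 1L, fp = 1L, fn = 0L))
})

test_that("the token criterion compares covered token/type triples", {
  doc <- "no chest pain today"
  tokens <- tokenize_document(doc, doc_id = "doc")
  gold <- toy_mention("problem", 3, 13, doc_id = "doc")    # chest pain
  pred <- toy_mention("problem", 3, 8, doc_id = "doc")     # chest only
  cnt <- match_mentions(gold, pred, "token", tokens = tokens)
  expect_equal(cnt, c(tp = 1L, fp = 0L, fn = 1L))
  expect_error(match_mentions(gold, pred, "token"),
               class = "nerlstm_value_error")
})

test_that("micro averaging sums counts before forming ratios", {
  r <- micro_average(list(c(tp = 1L, fp = 0L, fn = 0L),
                          c(tp = 0L, fp = 1L, fn = 1L)))
  expect_equal(c(r$precision, r$recall, r$f1), c(0.5, 0.5, 0.5))

  r0 <- micro_average(list(c(tp = 0L, fp = 0L, fn = 0L)))
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))

  r3 <- micro_average(list(c(tp = 3L, fp = 1L, fn = 2L)))
  expect_equal(r3$precision, 0.75)
  expect_equal(r3$recall, 0.6)
  expect_equal(r3$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
})

test_that("corpus evaluation reproduces hand-counted fixtures", {
  # two documents, three types, counts worked out by hand:
  # doc a: gold problem(0,10), test(12,16); pred problem(0,10), test(12,14),
  #        treatment(20,25)
  # doc b: gold treatment(0,5);             pred test(0,5)
  gold <- dplyr::bind_rows(
    toy_mention("problem", 0, 10, doc_id = "a"),
    toy_mention("test", 12, 16, doc_id = "a"),
    toy_mention("treatment", 0, 5, doc_id = "b"))
  pred <- dplyr::bind_rows(
    toy_mention("problem", 0, 10, doc_id = "a"),
    toy_mention("test", 12, 14, doc_id = "a"),
    toy_mention("treatment", 20, 25, doc_id = "a"),
    toy_mention("test", 0, 5, doc_id = "b"))
  res <- evaluate_corpus(gold, pred, criteria = c("exact", "inexact", "span"))
  all_rows <- res[res$type == "<all>", ]
  # exact: only problem(0,10) matches -> tp 1, fp 3, fn 2
  expect_equal(unlist(all_rows[all_rows$criterion == "exact",
                               c("tp", "fp", "fn")]),
               c(tp = 1L, fp = 3L, fn = 2L), ignore_attr = TRUE)
  # inexact adds test(12,14)~test(12,16) -> tp 2
  expect_equal(all_rows$tp[all_rows$criterion == "inexact"], 2L)
  # span additionally matches pred test(0,5) to gold treatment(0,5) -> tp 3
  expect_equal(all_rows$tp[all_rows$criterion == "span"], 3L)
  expect_equal(all_rows$precision[all_rows$criterion == "span"], 3 / 4)
  expect_equal(all_rows$recall[all_rows$criterion == "span"], 1)

  # per-type rows exist for each type under each criterion
  expect_true(all(c("problem", "test", "treatment") %in% res$type))

  # identical prediction: F1 = 1 everywhere; empty prediction: P = R = 0
  perfect <- evaluate_corpus(gold, gold, criteria = c("exact", "span"))
  expect_true(all(perfect$f1[perfect$type == "<all>"] == 1))
  none <- evaluate_corpus(gold, gold[0, ], criteria = "exact",
                          per_type = FALSE)
  expect_equal(c(none$precision, none$recall), c(0, 0))

  # unknown documents in predictions are an error naming them
  stray <- toy_mention("problem", 0, 3, doc_id = "zzz")
  expect_error(evaluate_corpus(gold, stray, criteria = "exact"),
               "zzz", class = "nerlstm_value_error")
})

test_that("criteria relax monotonically and matching is symmetric", {
  set.seed(61)
  types <- c("problem", "test", "treatment")
  rand_mentions <- function(n, doc) {
    starts <- sort(sample(0:200, n))
    tibble::tibble(doc_id = doc, type = sample(types, n, TRUE),
                   start = starts, end = starts + sample(2:12, n, TRUE))
  }
  for (rep in 1:20) {
    gold <- rand_mentions(sample(1:10, 1), "d")
    pred <- rand_mentions(sample(1:10, 1), "d")
    cnt <- vapply(c("exact", "inexact", "span"),
                  function(cr) match_mentions(gold, pred, cr)[["tp"]],
                  integer(1))
    expect_lte(cnt[["exact"]], cnt[["inexact"]])
    expect_lte(cnt[["inexact"]], cnt[["span"]])
    for (cr in c("exact", "inexact", "span", "type")) {
      a <- match_mentions(gold, pred, cr)
      b <- match_mentions(pred, gold, cr)
      expect_equal(a[["tp"]], b[["tp"]])
      expect_equal(a[["fp"]], b[["fn"]])
      expect_equal(a[["fn"]], b[["fp"]])
      expect_lte(a[["tp"]], min(nrow(gold), nrow(pred)))
    }
  }
})

test_that("evaluation plots build", {
  gold <- toy_mention("problem", 0, 10, doc_id = "a")
  res <- evaluate_corpus(gold, gold, criteria = c("exact", "span"))
  expect_s3_class(autoplot(res), "ggplot")
})
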