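mk_mentions <- function(starts, ends, types, pid = "p0001") {
  tibble::tibble(passage_id = pid, start = as.integer(starts),
                 end = as.integer(ends),
                 surface = strrep("x", ends - starts),
                 entity_type = types)
}

test_that("strict counting matches one-to-one on span and type", {
  g <- mk_mentions(c(0, 10, 20), c(5, 15, 25), c("A", "B", "A"))
  expect_equal(count_matches(g, g), tibble::tibble(tp = 3L, fp = 0L,
                                                   fn = 0L))
  g4 <- mk_mentions(c(0, 10, 20, 30), c(5, 15, 25, 35), rep("A", 4))
  p <- mk_mentions(c(0, 10, 50), c(5, 15, 55), rep("A", 3))
  expect_equal(count_matches(g4, p), tibble::tibble(tp = 2L, fp = 1L,
                                                    fn = 2L))
  expect_equal(count_matches(g4, g4[0, ]),
               tibble::tibble(tp = 0L, fp = 0L, fn = 4L))
  # a type mismatch on the same span is both a FP and a FN
  p2 <- mk_mentions(0, 5, "B")
  expect_equal(count_matches(mk_mentions(0, 5, "A"), p2),
               tibble::tibble(tp = 0L, fp = 1L, fn = 1L))
  # duplicated predictions match at most once
  p3 <- mk_mentions(c(0, 0), c(5, 5), c("A", "A"))
  expect_equal(count_matches(mk_mentions(0, 5, "A"), p3)$tp, 1L)
})

test_that("counts are permutation-invariant and conserve totals", {
  set.seed(61)
  for (i in 1:30) {
    g <- mk_mentions(sample(0:50, 8), sample(51:99, 8),
                     sample(c("A", "B"), 8, TRUE))
    p <- mk_mentions(sample(0:50, 6), sample(51:99, 6),
                     sample(c("A", "B"), 6, TRUE))
    c1 <- count_matches(g, p)
    c2 <- count_matches(g[sample(8), ], p[sample(6), ])
    expect_identical(c1, c2)
    expect_equal(c1$tp + c1$fn, nrow(g))
    expect_equal(c1$tp + c1$fp, nrow(p))
  }
})

test_that("metrics follow the defining formulas with 0/0 -> 0", {
  m <- ner_metrics(tibble::tibble(tp = 2L, fp = 1L, fn = 2L))
  expect_equal(round(m$precision, 3), 0.667)
  expect_equal(round(m$recall, 3), 0.5)
  expect_equal(round(m$f1, 3), 0.571)
  z <- ner_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 0L))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  eq <- ner_metrics(tibble::tibble(tp = 3L, fp = 1L, fn = 1L))
  expect_equal(eq$f1, eq$precision)  # harmonic mean of equal values
})

test_that("the F-measure reproduces published precision/recall pairings", {
  expect_equal(round(f_measure(70.7, 68.9), 1), 69.8)
  expect_equal(round(f_measure(90.1, 74.1), 1), 81.3)
  expect_equal(round(f_measure(75.3, 69.5), 1), 72.3)
  expect_equal(f_measure(0, 0), 0)
  expect_equal(f_measure(50, 50), 50)
})

test_that("k-fold splits partition evenly and deterministically", {
  f <- kfold_split(100, 10, 7)
  expect_equal(as.vector(table(f$fold)), rep(10L, 10))
  f33 <- kfold_split(33, 10, 7)
  sizes <- sort(as.vector(table(f33$fold)))
  expect_equal(sizes, c(rep(3L, 7), rep(4L, 3)))
  expect_identical(kfold_split(33, 10, 7), f33)
  expect_false(identical(kfold_split(33, 10, 8)$fold, f33$fold))
  expect_error(kfold_split(5, 10, 1), "at least")
})

test_that("IOB2 reading maps tagged runs to character spans", {
  f <- withr::local_tempfile(fileext = ".iob2")
  writeLines(c("Expression\tO", "of\tO", "EGR\tB-protein", "1\tI-protein"),
             f)
  co <- read_iob2(f)
  expect_equal(co$passages$text, "Expression of EGR 1")
  expect_equal(nrow(co$gold), 1L)
  expect_equal(co$gold$start, 14L)
  expect_equal(co$gold$end, 19L)
  expect_equal(co$gold$surface, "EGR 1")
  expect_equal(co$gold$entity_type, "protein")
})

test_that("empty IOB2 files read as empty corpora", {
  f <- withr::local_tempfile(fileext = ".iob2")
  writeLines(character(0), f)
  co <- read_iob2(f)
  expect_equal(nrow(co$passages), 0L)
  expect_equal(nrow(co$gold), 0L)
})

test_that("dangling I- tags error with the line, or repair when lenient", {
  f <- withr::local_tempfile(fileext = ".iob2")
  writeLines(c("alpha\tO", "beta\tI-DNA"), f)
  expect_error(read_iob2(f), "line 2")
  co <- read_iob2(f, lenient = TRUE)
  expect_equal(co$gold$entity_type, "DNA")
  expect_equal(co$gold$start, 6L)
  # type switch without B is also dangling
  f2 <- withr::local_tempfile(fileext = ".iob2")
  writeLines(c("alpha\tB-DNA", "beta\tI-RNA"), f2)
  expect_error(read_iob2(f2), "line 2")
})

test_that("IOB2 round-trips are exact both ways", {
  dict <- synth_dictionary(20, seed = 8)
  co <- synth_corpus(dict, 30, variant_rate = 0.3, seed = 8)
  f <- withr::local_tempfile(fileext = ".iob2")
  write_iob2(co, f)
  back <- read_iob2(f)
  expect_identical(back$passages$text, co$passages$text)
  key <- function(d) sort(paste(d$passage_id, d$start, d$end,
                                d$entity_type))
  expect_identical(key(back$gold), key(co$gold))
  f2 <- withr::local_tempfile(fileext = ".iob2")
  write_iob2(back, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("non-token-aligned mentions are rejected at write time", {
  passages <- tibble::tibble(passage_id = "p0001", text = "alpha beta")
  bad <- tibble::tibble(passage_id = "p0001", start = 2L, end = 7L,
                        surface = "pha b", entity_type = "X")
  f <- withr::local_tempfile(fileext = ".iob2")
  expect_error(write_iob2(passages, f, mentions = bad), "token-aligned")
})

test_that("evaluation objects expose overall, per-type and fold views", {
  dict <- synth_dictionary(15, seed = 9)
  co <- synth_corpus(dict, 30, variant_rate = 0, seed = 9)
  ex <- extract_corpus(co, dict)
  ev <- evaluate_mentions(co$gold, ex$mentions, k = 5, seed = 2)
  expect_equal(ev$overall$f1, 1)
  expect_true(all(ev$by_type$f1 == 1))
  expect_equal(nrow(ev$by_fold), 5L)
  expect_equal(mean(ev$by_fold$f1), 1)
  expect_identical(glance(ev), ev$overall)
  expect_identical(tidy(ev), ev$by_type)
  pl <- autoplot(ev)
  expect_s3_class(pl, "ggplot")
})
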