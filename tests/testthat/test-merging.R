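test_that("tokenization detaches edge punctuation with exact offsets", {
  t1 <- tokenize("E coli.")
  expect_equal(t1$text, c("E", "coli", "."))
  expect_equal(t1$start, c(0L, 2L, 6L))
  t2 <- tokenize("(EGR-1), really.")
  expect_equal(t2$text, c("(", "EGR-1", ")", ",", "really", "."))
  expect_equal(nrow(tokenize("")), 0L)
})

test_that("tokens always satisfy the slice invariant", {
  texts <- c("Expression of EGR 1 was measured.",
             "We studied (E coli) and B-Lymphocytes, twice.",
             "  spaced   out --- text  ", "x")
  for (txt in texts) {
    tk <- tokenize(txt)
    for (r in seq_len(nrow(tk))) {
      expect_identical(substr(txt, tk$start[r] + 1L,
                              tk$start[r] + nchar(tk$text[r])),
                       tk$text[r])
    }
    # tokens cover all non-whitespace characters, in order
    expect_identical(paste(tk$text, collapse = ""),
                     gsub("\\s+", "", txt))
  }
})

test_that("the default tagger follows its word-list and suffix rules", {
  tags <- default_pos_tagger(c("dopamine", "receptor", "was", "measured",
                               "the", "2", "rapidly", "chemical", "."))
  expect_identical(tags, c("NOUN", "NOUN", "VERB", "VERB", "OTHER", "NUM",
                           "OTHER", "ADJ", "OTHER"))
})

test_that("tagging fills pos, is idempotent, and accepts injected taggers", {
  tk <- tokenize("dopamine receptor binding")
  tagged <- pos_tag(tk)
  expect_false(anyNA(tagged$pos))
  expect_identical(pos_tag(tagged), tagged)
  all_noun <- function(w) rep("NOUN", length(w))
  expect_true(all(pos_tag(tk, all_noun)$pos == "NOUN"))
  bad <- function(w) rep("XYZ", length(w))
  expect_error(pos_tag(tk, bad), "tag")
})

test_that("nested same-start same-type noun mentions merge into the longer", {
  text <- "dopamine receptor levels"
  toks <- pos_tag(tokenize(text))
  m <- tibble::tibble(
    start = c(0L, 0L), end = c(8L, 17L),
    surface = c("dopamine", "dopamine receptor"),
    entity_type = "Chemicals and Drugs", score = c(0, 0))
  out <- merge_mentions(m, toks)
  expect_equal(nrow(out), 1L)
  expect_equal(out$surface, "dopamine receptor")
})

test_that("type or start mismatches block merging", {
  text <- "dopamine receptor levels"
  toks <- pos_tag(tokenize(text))
  m_type <- tibble::tibble(
    start = c(0L, 0L), end = c(8L, 17L),
    surface = c("dopamine", "dopamine receptor"),
    entity_type = c("Chemicals and Drugs", "Diseases"), score = 0)
  expect_equal(nrow(merge_mentions(m_type, toks)), 2L)
  m_start <- tibble::tibble(
    start = c(0L, 9L), end = c(8L, 17L),
    surface = c("dopamine", "receptor"),
    entity_type = "Chemicals and Drugs", score = 0)
  expect_equal(nrow(merge_mentions(m_start, toks)), 2L)
})

test_that("a verb inside the span blocks the noun-phrase condition", {
  text <- "dopamine was receptor"
  toks <- pos_tag(tokenize(text))
  m <- tibble::tibble(
    start = c(0L, 0L), end = c(8L, 21L),
    surface = c("dopamine", "dopamine was receptor"),
    entity_type = "Chemicals and Drugs", score = 0)
  expect_equal(nrow(merge_mentions(m, toks)), 2L)
})

test_that("stem-prefix nesting merges regardless of input row order", {
  text <- "dopamine kinase complex"
  toks <- pos_tag(tokenize(text))
  m <- tibble::tibble(
    start = c(0L, 0L), end = c(15L, 8L),
    surface = c("dopamine kinase", "dopamine"),
    entity_type = "Protein", score = 0)
  out <- merge_mentions(m, toks)
  expect_equal(nrow(out), 1L)
  expect_equal(out$surface, "dopamine kinase")
  # chains collapse to the longest span in one fixed point
  m3 <- tibble::tibble(
    start = 0L, end = c(8L, 15L, 23L),
    surface = c("dopamine", "dopamine kinase", "dopamine kinase complex"),
    entity_type = "Protein", score = 0)
  expect_equal(merge_mentions(m3, toks)$surface,
               "dopamine kinase complex")
  # equal-length identical spans are not merged into each other
  m2 <- tibble::tibble(
    start = c(0L, 0L), end = c(8L, 8L),
    surface = "dopamine", entity_type = "Protein", score = 0)
  expect_equal(nrow(merge_mentions(m2, toks)), 2L)
})

test_that("merging is idempotent and returns a subset of its input", {
  set.seed(51)
  for (i in 1:150) {
    fx <- rand_mention_set()
    once <- merge_mentions(fx$mentions, fx$tokens)
    twice <- merge_mentions(once, fx$tokens)
    expect_identical(once, twice)
    key <- function(d) paste(d$start, d$end, d$entity_type, d$score)
    expect_true(all(key(once) %in% key(fx$mentions)))
    # no surviving pair with equal (start, type) and stem-prefix nesting
    if (nrow(once) > 1L) {
      for (a in seq_len(nrow(once) - 1L)) {
        for (b in (a + 1L):nrow(once)) {
          if (once$start[a] == once$start[b] &&
              once$entity_type[a] == once$entity_type[b]) {
            sa <- porter_stem(tolower(strsplit(once$surface[a], " ")[[1]]))
            sb <- porter_stem(tolower(strsplit(once$surface[b], " ")[[1]]))
            shorter <- if (length(sa) <= length(sb)) sa else sb
            longer <- if (length(sa) <= length(sb)) sb else sa
            span_ok <- all(
              pos_tag(fx$tokens)$pos[
                fx$tokens$start < max(once$end[a], once$end[b]) &
                  fx$tokens$start + nchar(fx$tokens$text) >
                    once$start[a]] %in% c("NOUN", "ADJ", "NUM"))
            if (span_ok && once$end[a] != once$end[b]) {
              expect_false(identical(shorter,
                                     longer[seq_along(shorter)]))
            }
          }
        }
      }
    }
  }
})

test_that("mention order in the output is (start, longest first)", {
  set.seed(52)
  fx <- rand_mention_set()
  out <- merge_mentions(fx$mentions, fx$tokens)
  expect_false(is.unsorted(out$start))
  for (s in unique(out$start)) {
    lens <- out$end[out$start == s] - s
    expect_false(is.unsorted(rev(lens)))
  }
})
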