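test_that("partitioning absorbs the remainder into the last piece", {
  expect_identical(partition_string("abcde", 2), c("ab", "cde"))
  expect_identical(partition_string("abcd", 2), c("ab", "cd"))
  expect_identical(partition_string("a", 2), "a")
  expect_identical(partition_string("", 3), character(0))
  expect_identical(partition_string("abcdefg", 3), c("abc", "defg"))
  # concatenation invariant and length bounds on random strings
  set.seed(41)
  for (i in 1:50) {
    s <- rand_word(letters[1:4], 1, 15)
    L <- sample(1:4, 1)
    p <- partition_string(s, L)
    expect_identical(paste(p, collapse = ""), s)
    if (length(p) > 1L) {
      expect_true(all(nchar(p[-length(p)]) == L))
    }
    expect_lte(nchar(p[length(p)]), max(2L * L - 1L, nchar(s) * (nchar(s) < L)))
  }
})

test_that("box scores average the mismatch over all character pairs", {
  expect_equal(box_score("a", "a"), 0)
  expect_equal(box_score("a", "b"), 1)
  expect_equal(box_score("ab", "ab"), 0.5)
  expect_equal(box_score("aa", "aa"), 0)
  expect_equal(box_score("ab", "cde"), 1)
  expect_equal(box_score("ab", "a"), 0.5)
  expect_error(box_score("", "a"))
})

test_that("the aligned box weight scores identical pieces as zero", {
  expect_equal(box_score_aligned("ab", "ab"), 0)
  expect_equal(box_score_aligned("ab", "ba"), 1)
  expect_equal(box_score_aligned("abc", "abd"), 1 / 3)
  expect_equal(box_score_aligned("ab", "abcd"), 0.5)
})

test_that("lattices have the piece-count shape and box-score entries", {
  l <- build_lattice("ab", "ba", sped_params(piece_length = 1))
  expect_equal(l$scores, matrix(c(1, 0, 0, 1), 2, 2))
  l2 <- build_lattice("abc", "abc", sped_params(piece_length = 1))
  expect_equal(dim(l2$scores), c(3L, 3L))
  expect_true(all(diag(l2$scores) == 0))
  l3 <- build_lattice("abcd", "ab", sped_params(piece_length = 2))
  expect_equal(dim(l3$scores), c(1L, 2L))
})

test_that("graphs have the prescribed node and edge structure", {
  g <- build_graph(build_lattice("ab", "ba"), 1)
  expect_equal(length(g$nodes), 5L)
  expect_equal(nrow(g$edges), 6L)
  expect_equal(sum(g$edges$move == "diagonal"), 2L)
  g1 <- build_graph(build_lattice("a", "b"), 1)
  expect_equal(length(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 1L)
})

test_that("graphs are acyclic: every edge advances the grid position", {
  coord <- function(x) {
    vapply(x, function(v) {
      if (v == "source") return(0L)
      sum(as.integer(strsplit(gsub("[()]", "", v), ",")[[1]]))
    }, integer(1))
  }
  g <- build_graph(build_lattice("abcd", "xyz"), 0.5)
  expect_true(all(coord(g$edges$to) > coord(g$edges$from)))
})

test_that("shortest paths pick the minimum weight, then most edges", {
  # zero-cost diagonal available
  g <- build_graph(structure(list(scores = matrix(c(0, 1, 1, 0), 2, 2)),
                             class = "box_lattice"), 1)
  sp <- shortest_path(g)
  expect_equal(sp$weight, 0)
  expect_equal(sp$edge_count, 2L)
  expect_equal(sp$normalized, 0)
  # single box
  g1 <- build_graph(structure(list(scores = matrix(0.4, 1, 1)),
                              class = "box_lattice"), 1)
  sp1 <- shortest_path(g1)
  expect_equal(sp1$weight, 0.4)
  expect_equal(sp1$edge_count, 1L)
  # anti-diagonal forces weight 2 over 2 edges
  g2 <- build_graph(structure(list(scores = matrix(c(1, 0, 0, 1), 2, 2)),
                              class = "box_lattice"), 1)
  sp2 <- shortest_path(g2)
  expect_equal(sp2$weight, 2)
  expect_equal(sp2$normalized, 1)
})

test_that("common prefixes are measured on the exact strings", {
  expect_equal(common_prefix_length("abc", "abd"), 2L)
  expect_equal(common_prefix_length("x", "y"), 0L)
  expect_equal(common_prefix_length("dopamine", "dopamine"), 8L)
  expect_equal(common_prefix_length("", "abc"), 0L)
})

test_that("prefix re-scoring lowers scores, capped and clamped", {
  expect_equal(prefix_rescore(0.5, 2), 0.4)
  expect_equal(prefix_rescore(0.7, 0), 0.7)
  expect_equal(prefix_rescore(0.0, 3), 0.0)
  # cap: prefix 10 counts as 4
  expect_equal(prefix_rescore(0.5, 10), prefix_rescore(0.5, 4))
  set.seed(42)
  for (i in 1:50) {
    x <- runif(1); p <- sample(0:8, 1)
    expect_lte(prefix_rescore(x, p), x)
    expect_gte(prefix_rescore(x, p), 0)
  }
})

test_that("SPED reproduces the hand-traced distances", {
  expect_equal(sped_distance("abc", "abc"), 0)
  expect_equal(sped_distance("ab", "ba"), 1)
  expect_equal(sped_distance("ab", "ab", sped_params(piece_length = 2)),
               0.4)
  expect_equal(sped_distance("", ""), 0)
  expect_equal(sped_distance("", "abc"), 1)
  expect_equal(sped_distance("abc", ""), 1)
})

test_that("SPED is symmetric, in range, and zero on identity", {
  set.seed(43)
  alpha <- letters[1:6]
  for (i in 1:300) {
    s <- rand_word(alpha, 0, 12); t <- rand_word(alpha, 0, 12)
    d <- sped_distance(s, t)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, sped_distance(t, s))
  }
  for (i in 1:50) {
    s <- rand_word(alpha, 1, 12)
    expect_equal(sped_distance(s, s), 0)
  }
})

test_that("path weights sit between Levenshtein and Hamming at L = 1", {
  set.seed(44)
  alpha <- letters[1:5]
  for (i in 1:150) {
    s <- rand_word(alpha, 1, 12); t <- rand_word(alpha, 1, 12)
    w <- shortest_path(build_graph(build_lattice(s, t), 1))$weight
    expect_gte(w, as.numeric(adist(s, t)) - 1e-9)
    if (nchar(s) == nchar(t)) {
      expect_lte(w, hamming(s, t) + 1e-9)
    }
  }
})

test_that("the aligned weight variant keeps range, symmetry and identity", {
  set.seed(45)
  p <- sped_params(piece_length = 3, weight_fn = "aligned")
  for (i in 1:100) {
    s <- rand_word(letters[1:5], 1, 12); t <- rand_word(letters[1:5], 1, 12)
    d <- sped_distance(s, t, p)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, sped_distance(t, s, p))
  }
  expect_equal(sped_distance("abcdef", "abcdef",
                             sped_params(piece_length = 1,
                                         weight_fn = "aligned")), 0)
})

test_that("gap-cost tuning maximizes class separation with min-value ties", {
  expect_equal(tune_gap_cost(tibble::tibble(s = "a", t = "a",
                                            is_match = TRUE), 0.7), 0.7)
  pairs_tie <- tibble::tibble(s = c("ab", "cd"), t = c("ab", "cd"),
                              is_match = TRUE)
  expect_equal(tune_gap_cost(pairs_tie, c(0.4, 0.1, 1.0)), 0.1)
  # ("ab","b") scores (1+g)/2: separation grows with g, so 1.0 wins
  pairs <- tibble::tibble(s = c("ab", "ab"), t = c("ab", "b"),
                          is_match = c(TRUE, FALSE))
  expect_equal(tune_gap_cost(pairs, c(0.1, 1.0)), 1.0)
  expect_error(tune_gap_cost(pairs, numeric(0)))
})

test_that("the graph route and the distance front end agree", {
  set.seed(46)
  for (i in 1:40) {
    s <- rand_word(letters[1:5], 1, 10); t <- rand_word(letters[1:5], 1, 10)
    L <- sample(1:3, 1)
    p <- sped_params(piece_length = L)
    sp <- shortest_path(build_graph(build_lattice(s, t, p), p$gap_cost))
    expect_equal(sped_distance(s, t, p),
                 prefix_rescore(sp$normalized, common_prefix_length(s, t),
                                p))
  }
})
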