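# shared fixtures and independent oracles for the test suite

sample_dict <- function() {
  read_dict_tsv(system.file("extdata", "sample_dictionary.tsv",
                            package = "spedner"),
                default_source = "GENIA")
}

# independent reference: plain-R dynamic program for the weighted edit
# distance, sharing no code with the trie traversal it checks
ref_wed <- function(a, b, costs) {
  is_sep <- function(c) c %in% c("-", " ", "_")
  sub_cost <- function(x, y) {
    if (x == y) return(0)
    if (tolower(x) == tolower(y)) return(costs$substitute_case_only)
    if (is_sep(x) && is_sep(y)) return(costs$substitute_separator)
    costs$substitute_default
  }
  ind_cost <- function(x) {
    if (is_sep(x)) costs$indel_separator else costs$indel_default
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) d[i + 1, 1] <- d[i, 1] + ind_cost(av[i])
  for (j in seq_len(m)) d[1, j + 1] <- d[1, j] + ind_cost(bv[j])
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j] + sub_cost(av[i], bv[j]),
                             d[i, j + 1] + ind_cost(av[i]),
                             d[i + 1, j] + ind_cost(bv[j]))
    }
  }
  d[n + 1, m + 1]
}

# brute-force approximate lookup: filter every dictionary entry by distance
ref_lookup_keys <- function(keys, query, max_cost, costs) {
  d <- weighted_edit_distance(rep(query, length(keys)), keys, costs)
  sort(keys[d <= max_cost + 1e-9])
}

rand_word <- function(alphabet, min_len = 1L, max_len = 12L) {
  k <- sample(min_len:max_len, 1L)
  paste(sample(alphabet, k, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# random mention sets over a token-aligned passage, for merging properties
rand_mention_set <- function(vocab = c("alpha", "beta", "gamma", "delta",
                                       "receptor", "kinase", "cells")) {
  n_tok <- sample(4:8, 1L)
  words <- sample(vocab, n_tok, replace = TRUE)
  text <- paste(words, collapse = " ")
  toks <- pos_tag(tokenize(text))
  starts <- c(0L, cumsum(nchar(words) + 1L)[-n_tok])
  ends <- starts + nchar(words)
  n_m <- sample(2:6, 1L)
  a <- sample(n_tok, n_m, replace = TRUE)
  len <- pmin(n_tok - a + 1L, sample(1:3, n_m, replace = TRUE))
  m <- tibble::tibble(
    start = starts[a],
    end = ends[a + len - 1L],
    entity_type = sample(c("Protein", "DNA"), n_m, replace = TRUE),
    score = round(stats::runif(n_m), 3))
  m$surface <- substr(text, m$start + 1L, m$end)
  list(mentions = m, tokens = toks, text = text)
}

bioner_path <- function() {
  system.file("bioner", package = "spedner")
}

run_bioner <- function(args) {
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 shQuote(c(bioner_path(), args)), stdout = TRUE,
                 stderr = TRUE)
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
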