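#' Edit-operation cost table
#'
#' Per-operation costs for the weighted edit distance used in candidate
#' generation. Substitutions that only change letter case ("E" vs "e") and
#' substitutions within the separator class (`-`, space, `_`) are cheap,
#' because the spelling-variant families of gene/protein names differ almost
#' exclusively in case and separators; real letter edits stay expensive.
#'
#' @param substitute_default Cost of a general substitution.
#' @param substitute_case_only Cost of a case-only substitution.
#' @param substitute_separator Cost of a separator-for-separator substitution.
#' @param indel_default Cost of inserting/deleting a non-separator character.
#' @param indel_separator Cost of inserting/deleting a separator.
#' @return A `cost_table` list.
#' @examples
#' weighted_edit_distance("EGR-1", "Egr 1", cost_table())
#' @export
cost_table <- function(substitute_default = 1.0, substitute_case_only = 0.1,
                       substitute_separator = 0.1, indel_default = 1.0,
                       indel_separator = 0.2) {
  ct <- list(substitute_default = substitute_default,
             substitute_case_only = substitute_case_only,
             substitute_separator = substitute_separator,
             indel_default = indel_default,
             indel_separator = indel_separator)
  stopifnot(all(vapply(ct, is.numeric, logical(1))),
            all(unlist(ct) >= 0),
            substitute_case_only <= substitute_default,
            substitute_separator <= substitute_default,
            indel_separator <= indel_default)
  structure(ct, class = "cost_table")
}

#' Weighted edit distance between two strings
#'
#' Minimum total cost of an insert/delete/substitute script transforming `a`
#' into `b`, with per-operation costs from a [cost_table()]. With all-unit
#' costs this is the Levenshtein distance. Symmetric, and a metric when the
#' character costs are (the default table is).
#'
#' @param a,b Character vectors (recycled to a common length).
#' @param costs A [cost_table()].
#' @return Numeric vector of distances.
#' @examples
#' weighted_edit_distance("kitten", "sitting",
#'   cost_table(1, 1, 1, 1, 1))  # 3
#' @export
weighted_edit_distance <- function(a, b, costs = cost_table()) {
  stopifnot(inherits(costs, "cost_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) .wed_cpp(a[i], b[i], costs), numeric(1))
}

#' Build a trie index over dictionary surfaces
#'
#' Indexes the dictionary for approximate lookup. Keys are the normalized
#' surfaces by default; with `raw = TRUE` the verbatim surfaces are indexed
#' instead, which makes the lookup cost reflect case/separator differences
#' directly (useful when re-scoring raw forms).
#'
#' @param dict An [entity_dictionary()].
#' @param raw Index verbatim surfaces instead of normalized keys?
#' @param costs Default [cost_table()] for lookups against this index.
#' @return A `term_index` object.
#' @export
build_term_index <- function(dict, raw = FALSE, costs = cost_table()) {
  stopifnot(inherits(dict, "entity_dictionary"))
  keys <- if (raw) dict$surface else dict$normalized
  ok <- nzchar(keys)
  keys_u <- sort(unique(keys[ok]), method = "radix")
  structure(list(
    trie = .trie_build_cpp(keys_u),
    keys = keys_u,
    entry_key = match(keys, keys_u),  # NA for dropped empty keys
    dict = dict,
    raw = raw,
    costs = costs,
    cache = new.env(parent = emptyenv())  # memoized lookups, shared
  ), class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", length(x$keys), " keys over ", nrow(x$dict),
      " entries (", if (x$raw) "raw" else "normalized", " surfaces)\n",
      sep = "")
  invisible(x)
}

.empty_candidates <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- tibble::tibble(surface = character(),
                              normalized = character(),
                              entity_type = character(),
                              source = character(),
                              concept_id = character(), cost = numeric())
    }
    memo
  }
})

#' Approximate dictionary lookup
#'
#' Returns exactly the dictionary entries whose weighted edit distance to the
#' query is at most `max_cost`, found by cost-pruned trie traversal
#' (equivalent to, but much faster than, scanning every entry). For a
#' normalized index the query is normalized first.
#'
#' @param index A [build_term_index()] object.
#' @param query Query string.
#' @param max_cost Cost threshold (>= 0). Default 0.6 admits the full
#'   case/separator variant family of a name while rejecting single-letter
#'   real edits under the default cost table.
#' @param costs Optional [cost_table()] override.
#' @return Tibble of candidate matches (dictionary columns plus `cost`),
#'   sorted by ascending cost then surface.
#' @export
approx_lookup <- function(index, query, max_cost = 0.6, costs = NULL) {
  stopifnot(inherits(index, "term_index"), length(query) == 1L,
            is.numeric(max_cost), max_cost >= 0)
  costs <- costs %||% index$costs
  q <- if (index$raw) as.character(query) else normalize_term(query)
  .lookup_uncached(index, q, max_cost, costs)
}

.lookup_uncached <- function(index, q, max_cost, costs) {
  hits <- .trie_lookup_cpp(index$trie, q, max_cost, costs)
  if (!nrow(hits)) return(.empty_candidates())
  rows <- which(index$entry_key %in% hits$key_id)
  out <- index$dict[rows, , drop = FALSE]
  out$cost <- hits$cost[match(index$entry_key[rows], hits$key_id)]
  out <- tibble::as_tibble(out)
  out[order(out$cost, out$surface, method = "radix"), ]
}

# memoized on the index: corpus extraction revisits the same span texts
.lookup_cached <- function(index, surf, max_cost) {
  key <- paste0(format(max_cost), "\1", surf)
  hit <- index$cache[[key]]
  if (!is.null(hit)) {
    return(if (is.logical(hit)) NULL else hit)
  }
  q <- if (index$raw) surf else normalize_term(surf)
  cand <- .lookup_uncached(index, q, max_cost, index$costs)
  index$cache[[key]] <- if (nrow(cand)) cand else NA
  if (nrow(cand)) cand else NULL
}

#' Scan a passage for approximate dictionary matches
#'
#' Looks up every token-boundary-aligned span of 1..`max_span_tokens` tokens
#' and keeps the spans with at least one candidate within `max_cost`. Span
#' offsets are 0-based half-open character positions into the original text.
#'
#' @param index A [build_term_index()] object.
#' @param text Passage text.
#' @param max_cost Lookup threshold, as in [approx_lookup()].
#' @param max_span_tokens Longest candidate span, in tokens (>= 1).
#' @return Tibble with `start`, `end`, `surface` and a `candidates`
#'   list-column of candidate tibbles, in ascending (start, end) order.
#' @export
scan_passage <- function(index, text, max_cost = 0.6, max_span_tokens = 5L) {
  stopifnot(inherits(index, "term_index"), max_span_tokens >= 1L)
  toks <- tokenize(text)
  if (!nrow(toks)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          surface = character(), candidates = list()))
  }
  n <- nrow(toks)
  tok_end <- toks$start + nchar(toks$text)
  starts <- integer(0); ends <- integer(0); surfs <- character(0)
  cands <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_span_tokens - 1L)) {
      start <- toks$start[i]
      end <- tok_end[j]
      surf <- substr(text, start + 1L, end)
      cand <- .lookup_cached(index, surf, max_cost)
      if (!is.null(cand)) {
        starts <- c(starts, start); ends <- c(ends, end)
        surfs <- c(surfs, surf); cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  out <- tibble::tibble(start = starts, end = ends, surface = surfs,
                        candidates = cands)
  out[order(out$start, out$end), ]
}
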