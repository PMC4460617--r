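#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end extractor. Modes mirror the method's
#' experimental arms: `"all"` combines approximate matching, SPED re-scoring
#' and context/POS merging; `"context_only"` keeps exact (normalized)
#' matches plus merging; `"sped_only"` uses approximate matching with SPED
#' but no merging; `"exact_only"` is the verbatim-dictionary baseline (raw
#' surface lookup, no soft matching, no merging).
#'
#' @param mode Extraction arm.
#' @param max_cost Approximate-lookup threshold, see [approx_lookup()].
#' @param max_span_tokens Longest candidate span in tokens.
#' @param sped [sped_params()] for candidate re-scoring.
#' @param sped_accept_threshold Keep SPED-scored candidates at or below this
#'   distance (default 0.3 under the default [sped_params()]).
#' @param source_priority Optional source ordering overriding the
#'   dictionary's own.
#' @param stemming Stem normalized keys and queries? Default `FALSE`.
#' @param costs [cost_table()] for the lookup phase.
#' @param pure_noun Restrict merging to plain-NOUN spans
#'   (see [merge_mentions()]).
#' @param seed Optional integer recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("all", "context_only", "sped_only",
                                     "exact_only"),
                            max_cost = 0.6, max_span_tokens = 5L,
                            sped = sped_params(),
                            sped_accept_threshold = 0.3,
                            source_priority = NULL, stemming = FALSE,
                            costs = cost_table(), pure_noun = FALSE,
                            seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(max_cost >= 0, max_span_tokens >= 1L,
            inherits(sped, "sped_params"),
            sped_accept_threshold >= 0, sped_accept_threshold <= 1,
            inherits(costs, "cost_table"))
  structure(list(mode = mode, max_cost = max_cost,
                 max_span_tokens = as.integer(max_span_tokens), sped = sped,
                 sped_accept_threshold = sped_accept_threshold,
                 source_priority = source_priority, stemming = stemming,
                 costs = costs, pure_noun = pure_noun, seed = seed),
            class = "pipeline_config")
}

.empty_mentions <- function(with_id = FALSE) {
  m <- tibble::tibble(start = integer(), end = integer(),
                      surface = character(), entity_type = character(),
                      score = numeric(), source = character(),
                      matched_surface = character())
  if (with_id) m <- tibble::add_column(m, passage_id = character(),
                                       .before = 1L)
  m
}

.empty_trace <- function() {
  tibble::tibble(span_start = integer(), span_end = integer(),
                 span_surface = character(), event = character(),
                 entity_type = character(), score = numeric(),
                 n_candidates = integer())
}

# trace accumulator: plain parallel vectors, materialized once at the end
.trace_new <- function() {
  e <- new.env(parent = emptyenv())
  e$span_start <- integer(0); e$span_end <- integer(0)
  e$span_surface <- character(0); e$event <- character(0)
  e$entity_type <- character(0); e$score <- numeric(0)
  e$n_candidates <- integer(0)
  e
}

.trace_add <- function(tr, start, end, surface, event, entity_type = NA,
                       score = NA, n_candidates = NA) {
  tr$span_start <- c(tr$span_start, as.integer(start))
  tr$span_end <- c(tr$span_end, as.integer(end))
  tr$span_surface <- c(tr$span_surface, surface)
  tr$event <- c(tr$event, event)
  tr$entity_type <- c(tr$entity_type, as.character(entity_type))
  tr$score <- c(tr$score, as.numeric(score))
  tr$n_candidates <- c(tr$n_candidates, as.integer(n_candidates))
}

.trace_build <- function(tr) {
  tibble::tibble(span_start = tr$span_start, span_end = tr$span_end,
                 span_surface = tr$span_surface, event = tr$event,
                 entity_type = tr$entity_type, score = tr$score,
                 n_candidates = tr$n_candidates)
}

# best candidate under (score, priority rank, longest surface, lexicographic)
.best_candidate <- function(cand, priority) {
  rank <- match(cand$source, priority)
  rank[is.na(rank)] <- length(priority) + 1L
  ord <- order(cand$score, rank, -nchar(cand$surface), cand$surface,
               method = "radix")
  cand[ord[1L], , drop = FALSE]
}

#' Extract entity mentions from a passage
#'
#' The full hybrid extraction algorithm: approximate trie lookup proposes
#' candidate (span, entry) pairs; a span whose normalized text equals a
#' candidate's normalized surface short-circuits to that entry with score 0;
#' remaining candidates are re-scored with [sped_distance()] on normalized
#' forms (the common-prefix credit measured on the raw forms) and kept below
#' the acceptance threshold; the best candidate per span wins by lowest
#' score, then source priority, then longest surface, then lexicographic
#' order; nested same-start mentions are then merged by POS/stem cues and
#' residual same-type overlaps resolved keeping the lowest-score, then
#' longest, mention. Deterministic for identical inputs.
#'
#' @param text Passage text.
#' @param dictionary Non-empty [entity_dictionary()].
#' @param config [pipeline_config()].
#' @param index Optional prebuilt [build_term_index()] matching `config`
#'   (reused across passages for speed).
#' @return An `ner_extraction`: list with `mentions` (tibble `start`, `end`,
#'   `surface`, `entity_type`, `score`, `source`, `matched_surface`) and
#'   `trace` (per-span record of short-circuits, scores and merge events).
#' @examples
#' dict <- entity_dictionary(data.frame(
#'   surface = "EGR-1", entity_type = "Protein", source = "GENIA"))
#' extract_entities("Expression of EGR 1 was measured", dict)
#' @export
extract_entities <- function(text, dictionary, config = pipeline_config(),
                             index = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dictionary) || nrow(dictionary) == 0L) {
    stop("cannot extract with an empty dictionary")
  }
  res <- structure(list(mentions = .empty_mentions(), trace = .empty_trace(),
                        text = text, config = config),
                   class = "ner_extraction")
  if (is.na(text) || !nzchar(text)) return(res)

  raw_mode <- config$mode == "exact_only"
  if (is.null(index)) {
    index <- build_term_index(dictionary, raw = raw_mode,
                              costs = config$costs)
  } else {
    stopifnot(inherits(index, "term_index"), index$raw == raw_mode)
  }
  priority <- config$source_priority %||% source_priority(dictionary)
  max_cost <- if (raw_mode) 0 else config$max_cost
  spans <- scan_passage(index, text, max_cost, config$max_span_tokens)

  mentions <- list()
  tr <- .trace_new()
  for (r in seq_len(nrow(spans))) {
    s <- spans$start[r]; e <- spans$end[r]; surf <- spans$surface[r]
    cand <- spans$candidates[[r]]
    if (raw_mode) {
      exact <- cand[cand$surface == surf, , drop = FALSE]
      if (!nrow(exact)) next
      exact$score <- 0
      best <- .best_candidate(exact, priority)
      .trace_add(tr, s, e, surf, "short_circuit", best$entity_type, 0,
                 nrow(cand))
    } else {
      span_norm <- normalize_term(surf, use_stemming = config$stemming)
      exact <- cand[cand$normalized == span_norm, , drop = FALSE]
      if (nrow(exact)) {
        exact$score <- 0
        best <- .best_candidate(exact, priority)
        .trace_add(tr, s, e, surf, "short_circuit", best$entity_type, 0,
                   nrow(cand))
      } else if (config$mode == "context_only") {
        .trace_add(tr, s, e, surf, "no_exact_match",
                   n_candidates = nrow(cand))
        next
      } else {
        cand$score <- vapply(seq_len(nrow(cand)), function(i) {
          sped_distance(
            span_norm, cand$normalized[i], config$sped,
            prefix_length = common_prefix_length(surf, cand$surface[i]))
        }, numeric(1))
        keep <- cand[cand$score <= config$sped_accept_threshold + 1e-12, ,
                     drop = FALSE]
        if (!nrow(keep)) {
          .trace_add(tr, s, e, surf, "sped_rejected",
                     n_candidates = nrow(cand))
          next
        }
        best <- .best_candidate(keep, priority)
        .trace_add(tr, s, e, surf, "sped_selected", best$entity_type,
                   best$score, nrow(cand))
      }
    }
    mentions[[length(mentions) + 1L]] <- list(
      start = as.integer(s), end = as.integer(e), surface = surf,
      entity_type = best$entity_type, score = best$score,
      source = best$source, matched_surface = best$surface)
  }

  m <- if (length(mentions)) {
    tibble::tibble(
      start = vapply(mentions, `[[`, integer(1), "start"),
      end = vapply(mentions, `[[`, integer(1), "end"),
      surface = vapply(mentions, `[[`, character(1), "surface"),
      entity_type = vapply(mentions, `[[`, character(1), "entity_type"),
      score = vapply(mentions, `[[`, numeric(1), "score"),
      source = vapply(mentions, `[[`, character(1), "source"),
      matched_surface = vapply(mentions, `[[`, character(1),
                               "matched_surface"))
  } else {
    .empty_mentions()
  }

  if (nrow(m) && config$mode %in% c("all", "context_only")) {
    toks <- pos_tag(tokenize(text))
    merged <- merge_mentions(m, toks, pure_noun = config$pure_noun)
    gone <- dplyr::anti_join(m, merged,
                             by = c("start", "end", "entity_type"))
    for (r in seq_len(nrow(gone))) {
      .trace_add(tr, gone$start[r], gone$end[r], gone$surface[r],
                 "merged_away", gone$entity_type[r], gone$score[r])
    }
    m <- merged
  }

  # cross-span overlap resolution within a type: lowest score, then longest
  if (nrow(m) > 1L) {
    ord <- order(m$score, -(m$end - m$start), m$start, method = "radix")
    keep <- rep(TRUE, nrow(m))
    for (a in seq_along(ord)) {
      i <- ord[a]
      if (!keep[i]) next
      for (b in seq_along(ord)) {
        if (b <= a) next
        j <- ord[b]
        if (!keep[j]) next
        if (m$entity_type[i] == m$entity_type[j] &&
            m$start[i] < m$end[j] && m$start[j] < m$end[i]) {
          keep[j] <- FALSE
          .trace_add(tr, m$start[j], m$end[j], m$surface[j],
                     "overlap_dropped", m$entity_type[j], m$score[j])
        }
      }
    }
    m <- m[keep, , drop = FALSE]
  }

  m <- m[order(m$start, m$end), , drop = FALSE]
  for (r in seq_len(nrow(m))) {
    .trace_add(tr, m$start[r], m$end[r], m$surface[r], "reported",
               m$entity_type[r], m$score[r])
  }
  res$mentions <- m
  res$trace <- .trace_build(tr)
  res
}

#' @export
print.ner_extraction <- function(x, ...) {
  cat("<ner_extraction> ", nrow(x$mentions), " mentions (mode ",
      x$config$mode, ")\n", sep = "")
  print(x$mentions)
  invisible(x)
}

#' Extract mentions from every passage of a corpus
#'
#' Vectorized driver over a passages tibble (or a [synth_corpus()]); the
#' term index is built once and reused.
#'
#' @param passages Tibble with `passage_id` and `text`, or a `synth_corpus`.
#' @param dictionary Non-empty [entity_dictionary()].
#' @param config [pipeline_config()].
#' @return An `ner_corpus_extraction`: list with `mentions` (tibble keyed by
#'   `passage_id`) and `traces` (list of per-passage traces).
#' @export
extract_corpus <- function(passages, dictionary,
                           config = pipeline_config()) {
  if (inherits(passages, "synth_corpus")) passages <- passages$passages
  passages <- tibble::as_tibble(passages)
  stopifnot(all(c("passage_id", "text") %in% names(passages)))
  index <- build_term_index(dictionary, raw = config$mode == "exact_only",
                            costs = config$costs)
  out <- purrr::map2(passages$text, passages$passage_id, function(txt, pid) {
    ex <- extract_entities(txt, dictionary, config, index = index)
    if (nrow(ex$mentions)) {
      ex$mentions <- tibble::add_column(ex$mentions, passage_id = pid,
                                        .before = 1L)
    }
    ex
  })
  mentions <- dplyr::bind_rows(lapply(out, `[[`, "mentions"))
  if (!nrow(mentions)) mentions <- .empty_mentions(with_id = TRUE)
  structure(list(mentions = mentions,
                 traces = stats::setNames(lapply(out, `[[`, "trace"),
                                          passages$passage_id),
                 passages = passages, config = config),
            class = "ner_corpus_extraction")
}

#' @export
print.ner_corpus_extraction <- function(x, ...) {
  cat("<ner_corpus_extraction> ", nrow(x$mentions), " mentions over ",
      nrow(x$passages), " passages (mode ", x$config$mode, ")\n", sep = "")
  invisible(x)
}
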