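#' Neutral filler vocabulary
#'
#' The fixed 50-word list from which synthetic passages draw their
#' non-entity tokens. Words whose normalized form collides with a dictionary
#' surface are filtered out at generation time.
#'
#' @return Character vector of 50 lowercase words.
#' @export
filler_vocabulary <- function() {
  c("study", "analysis", "results", "levels", "values", "samples", "groups",
    "data", "method", "approach", "role", "effect", "effects", "response",
    "responses", "pathway", "process", "mechanism", "function", "activity",
    "signal", "signals", "condition", "conditions", "treatment", "control",
    "controls", "experiment", "experiments", "assay", "assays", "culture",
    "cultures", "tissue", "tissues", "patient", "patients", "subject",
    "subjects", "model", "models", "test", "tests", "evidence", "outcome",
    "outcomes", "change", "changes", "factor", "factors")
}

.synth_type_pool <- c("Protein", "DNA", "RNA", "Cell Line", "Cell Type")

#' Generate a synthetic entity dictionary
#'
#' Draws gene-symbol-like surfaces (short consonant-heavy uppercase letter
#' blocks, optionally hyphenated with a digit, occasionally two-word) with
#' distinct normalized keys, spread across sources and entity types.
#' Deterministic for a given seed.
#'
#' @param n_terms Number of entries (>= 1).
#' @param seed Integer seed.
#' @param sources Source names to spread entries over.
#' @param types Entity-type labels to draw from.
#' @return An [entity_dictionary()].
#' @examples
#' synth_dictionary(5, seed = 7)
#' @export
synth_dictionary <- function(n_terms, seed,
                             sources = c("GENIA", "MeSH", "UMLS"),
                             types = .synth_type_pool) {
  stopifnot(n_terms >= 1L, length(sources) >= 1L, length(types) >= 1L)
  consonants <- strsplit("BCDFGHJKLMNPQRSTVWXZ", "")[[1]]
  withr::with_seed(as.integer(seed), {
    seen <- character(0)
    surfaces <- character(n_terms)
    for (i in seq_len(n_terms)) {
      repeat {
        block <- function() {
          paste(sample(consonants, sample(3:5, 1), replace = TRUE),
                collapse = "")
        }
        surf <- block()
        if (stats::runif(1) < 0.5) {
          surf <- paste0(surf, "-", sample(1:9, 1))
        }
        if (stats::runif(1) < 0.2) surf <- paste(surf, block())
        key <- normalize_term(surf)
        if (!key %in% seen) break
      }
      seen <- c(seen, key)
      surfaces[i] <- surf
    }
    entity_dictionary(tibble::tibble(
      surface = surfaces,
      entity_type = sample(types, n_terms, replace = TRUE),
      source = sample(sources, n_terms, replace = TRUE),
      concept_id = sprintf("SYN:%04d", seq_len(n_terms))
    ), source_priority = sources)
  })
}

#' Generate a synthetic annotated corpus
#'
#' Builds passages that embed 1-5 dictionary terms separated by filler
#' tokens from [filler_vocabulary()] (filtered so no filler collides with a
#' dictionary surface). Each embedded term is independently replaced by one
#' of its [generate_variants()] with probability `variant_rate`, emulating
#' the case/separator spelling variation of names like "EGR-1". Gold
#' mentions record the span actually written (0-based, half-open) and the
#' entity type the dictionary's source priority assigns to that surface.
#' Identical arguments give byte-identical corpora.
#'
#' @param dictionary Non-empty [entity_dictionary()] (when `n_passages` > 0).
#' @param n_passages Number of passages (>= 0).
#' @param variant_rate Probability in `[0, 1]` that a written term is a
#'   spelling variant rather than the verbatim dictionary surface.
#' @param seed Integer seed.
#' @return A `synth_corpus`: list with `passages` (tibble `passage_id`,
#'   `text`), `gold` (tibble `passage_id`, `start`, `end`, `surface`,
#'   `entity_type`), `dictionary`, `seed`, `variant_rate`.
#' @export
synth_corpus <- function(dictionary, n_passages, variant_rate = 0, seed = 1L) {
  stopifnot(n_passages >= 0L, variant_rate >= 0, variant_rate <= 1)
  empty <- list(
    passages = tibble::tibble(passage_id = character(), text = character()),
    gold = tibble::tibble(passage_id = character(), start = integer(),
                          end = integer(), surface = character(),
                          entity_type = character()),
    dictionary = dictionary, seed = as.integer(seed),
    variant_rate = variant_rate)
  class(empty) <- "synth_corpus"
  if (n_passages == 0L) return(empty)
  if (is.null(dictionary) || nrow(dictionary) == 0L) {
    stop("a non-empty dictionary is required to generate passages")
  }
  filler <- filler_vocabulary()[
    !normalize_term(filler_vocabulary()) %in% dictionary$normalized]
  if (length(filler) < 5L) stop("filler vocabulary exhausted by collisions")
  priority <- source_priority(dictionary)
  # one representative entry per normalized key, resolved exactly as the
  # extraction stage resolves ties: priority rank, longest, lexicographic
  reps <- .resolve_representatives(dictionary, priority)

  withr::with_seed(as.integer(seed), {
    passages <- vector("list", n_passages)
    gold <- vector("list", n_passages)
    for (p in seq_len(n_passages)) {
      n_terms <- sample(1:5, 1)
      rows <- reps[sample(nrow(reps), n_terms, replace = TRUE), ,
                   drop = FALSE]
      chunks <- character(0)
      is_term <- logical(0)
      term_type <- character(0)
      add_filler <- function() {
        paste(sample(filler, sample(2:5, 1), replace = TRUE), collapse = " ")
      }
      chunks <- add_filler(); is_term <- FALSE; term_type <- NA_character_
      for (k in seq_len(n_terms)) {
        surf <- rows$surface[k]
        if (stats::runif(1) < variant_rate) {
          vs <- generate_variants(surf)
          if (length(vs)) surf <- sample(vs, 1)
        }
        chunks <- c(chunks, surf, add_filler())
        is_term <- c(is_term, TRUE, FALSE)
        term_type <- c(term_type, rows$entity_type[k], NA_character_)
      }
      text <- paste(chunks, collapse = " ")
      ends <- cumsum(nchar(chunks) + 1L) - 1L
      starts <- c(0L, utils::head(ends, -1L) + 1L)
      pid <- sprintf("p%04d", p)
      passages[[p]] <- tibble::tibble(passage_id = pid, text = text)
      gold[[p]] <- tibble::tibble(
        passage_id = pid,
        start = starts[is_term], end = ends[is_term],
        surface = chunks[is_term], entity_type = term_type[is_term])
    }
    out <- empty
    out$passages <- dplyr::bind_rows(passages)
    out$gold <- dplyr::bind_rows(gold)
    out
  })
}

# best entry per normalized key under the extraction tie-break
.resolve_representatives <- function(dictionary, priority) {
  d <- tibble::as_tibble(dictionary)
  d$.rank <- match(d$source, priority)
  d |>
    dplyr::arrange(.data$normalized, .data$.rank,
                   -nchar(.data$surface), .data$surface) |>
    dplyr::distinct(.data$normalized, .keep_all = TRUE) |>
    dplyr::select(-".rank")
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus> ", nrow(x$passages), " passages, ", nrow(x$gold),
      " gold mentions, variant_rate ", x$variant_rate, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}
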