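#' Normalize an entity term
#'
#' Maps the spelling-variant family of a biomedical name onto a single key:
#' lowercases, replaces hyphens/underscores with spaces, collapses whitespace
#' runs, and strips leading/trailing punctuation, so that "EGR-1", "Egr 1",
#' "egr-1" and "egr 1" all normalize to `"egr 1"`. Optionally Porter-stems
#' each token. The map is idempotent.
#'
#' @param term Character vector of terms.
#' @param use_stemming Stem each whitespace-delimited token with
#'   [porter_stem()]? Default `FALSE`; dictionary keys are unstemmed, stems
#'   are used by the mention-merging stage.
#' @return Character vector of normalized terms ("" for empty input).
#' @examples
#' normalize_term(c("EGR-1", "Egr 1", "(E coli)."))
#' normalize_term("Lymphocytes", use_stemming = TRUE)
#' @export
normalize_term <- function(term, use_stemming = FALSE) {
  x <- tolower(gsub("[-_]", " ", as.character(term)))
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x <- trimws(gsub("[[:space:]]+", " ", x))
  if (use_stemming) {
    x <- vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
      paste(porter_stem(tok), collapse = " ")
    }, character(1))
  }
  x[is.na(term)] <- NA_character_
  x
}

# apply a case pattern to every alphabetic run, leaving digits/punctuation
.case_runs <- function(term, pattern = c("upper", "capital", "lower")) {
  pattern <- match.arg(pattern)
  m <- gregexpr("[A-Za-z]+", term)[[1]]
  if (m[1] == -1L) return(term)
  out <- term
  for (i in seq_along(m)) {
    start <- m[i]
    len <- attr(m, "match.length")[i]
    run <- substr(out, start, start + len - 1L)
    run <- switch(pattern,
      upper = toupper(run),
      lower = tolower(run),
      capital = paste0(toupper(substr(run, 1L, 1L)), tolower(substring(run, 2L)))
    )
    substr(out, start, start + len - 1L) <- run
  }
  out
}

#' Spelling variants of a term
#'
#' Deterministically enumerates the case/separator variant family of a name,
#' e.g. `"EGR-1"` yields `"Egr-1"`, `"egr-1"`, `"EGR 1"`, `"Egr 1"`,
#' `"egr 1"`. Case patterns (UPPER, Capitalized, lower, applied to alphabetic
#' runs) are crossed with separator substitutions (hyphen to space, space to
#' hyphen, unchanged); the input itself is excluded. Every variant normalizes
#' to the same key as the input.
#'
#' @param term A single non-empty term.
#' @return Character vector of distinct variants (possibly empty).
#' @examples
#' generate_variants("EGR-1")
#' @export
generate_variants <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, nzchar(term))
  seps <- list(
    identity,
    function(x) gsub("-", " ", x, fixed = TRUE),
    function(x) gsub(" ", "-", x, fixed = TRUE)
  )
  out <- character(0)
  for (cp in c("upper", "capital", "lower")) {
    cased <- .case_runs(term, cp)
    for (f in seps) out <- c(out, f(cased))
  }
  setdiff(unique(out), term)
}
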