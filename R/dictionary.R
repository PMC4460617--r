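#' Entity dictionaries
#'
#' An entity dictionary is a tibble with one row per (normalized surface,
#' entity type, source) triple and columns `surface`, `normalized`,
#' `entity_type`, `source`, `concept_id`, plus a `source_priority` attribute:
#' the ordered source names used to break type ties at extraction time.
#' Conflicting types for the same surface across sources are deliberately
#' retained; disambiguation happens during extraction. Surfaces that
#' normalize to the empty string (pure punctuation) are dropped, since no
#' text span can ever match them.
#'
#' @param entries Data frame with at least `surface` and `entity_type`;
#'   optional `source` (default `"user"`) and `concept_id`.
#' @param source_priority Character vector ordering the sources; defaults to
#'   first appearance order. Must cover every source present.
#' @param stem_keys Stem normalized keys with [porter_stem()]? Default off.
#' @return An `entity_dictionary` tibble.
#' @examples
#' entity_dictionary(data.frame(
#'   surface = c("EGR-1", "B-Lymphocytes"),
#'   entity_type = c("Protein", "Anatomy")
#' ))
#' @export
entity_dictionary <- function(entries, source_priority = NULL,
                              stem_keys = FALSE) {
  if (is.null(entries) || nrow(as.data.frame(entries)) == 0L) {
    d <- tibble::tibble(surface = character(), normalized = character(),
                        entity_type = character(), source = character(),
                        concept_id = character())
    return(.as_dictionary(d, source_priority %||% character()))
  }
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("surface", "entity_type") %in% names(entries)))
  if (!"source" %in% names(entries)) entries$source <- "user"
  if (!"concept_id" %in% names(entries)) entries$concept_id <- NA_character_
  if (any(!nzchar(entries$surface)) || anyNA(entries$surface)) {
    stop("dictionary surfaces must be non-empty")
  }
  if (any(!nzchar(entries$entity_type)) || anyNA(entries$entity_type)) {
    stop("entity types must be non-empty")
  }
  d <- entries |>
    dplyr::mutate(
      surface = as.character(.data$surface),
      normalized = normalize_term(.data$surface, use_stemming = stem_keys),
      entity_type = as.character(.data$entity_type),
      source = as.character(.data$source),
      concept_id = as.character(.data$concept_id)
    ) |>
    # surfaces made only of punctuation/separators normalize to "" and can
    # never be matched; drop them
    dplyr::filter(nzchar(.data$normalized)) |>
    dplyr::distinct(.data$normalized, .data$entity_type, .data$source,
                    .keep_all = TRUE) |>
    dplyr::select("surface", "normalized", "entity_type", "source",
                  "concept_id")
  sources <- unique(d$source)
  if (is.null(source_priority)) source_priority <- sources
  missing <- setdiff(sources, source_priority)
  if (length(missing)) {
    stop("sources absent from priority: ", paste(missing, collapse = ", "))
  }
  .as_dictionary(d, source_priority)
}

.as_dictionary <- function(d, priority) {
  attr(d, "source_priority") <- priority
  class(d) <- unique(c("entity_dictionary", class(tibble::tibble())))
  d
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat("<entity_dictionary> ", nrow(x), " entries, ",
      length(unique(x$entity_type)), " types, sources: ",
      paste(source_priority(x), collapse = " > "), "\n", sep = "")
  NextMethod()
}

#' Source priority of a dictionary
#' @param dict An `entity_dictionary`.
#' @return Ordered character vector of source names.
#' @export
source_priority <- function(dict) {
  attr(dict, "source_priority") %||% unique(dict$source)
}

#' Read a dictionary from a TSV file
#'
#' Tab-separated UTF-8 with columns surface, entity_type, and optionally
#' source and concept_id; lines starting with `#` are comments. Rows that
#' collapse to the same (normalized, entity_type, source) triple are merged.
#'
#' @param path File path.
#' @param default_source Source assigned to rows lacking one; defaults to the
#'   file name without extension.
#' @param stem_keys Passed to [entity_dictionary()].
#' @return An `entity_dictionary`.
#' @export
read_dict_tsv <- function(path, default_source = NULL, stem_keys = FALSE) {
  stopifnot(file.exists(path))
  default_source <- default_source %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(entity_dictionary(NULL))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed dictionary line ", idx[which(nf < 2L)[1]], " in ", path,
         ": expected at least 2 tab-separated fields")
  }
  entity_dictionary(tibble::tibble(
    surface = vapply(fields, `[`, "", 1L),
    entity_type = vapply(fields, `[`, "", 2L),
    source = ifelse(nf >= 3L, vapply(fields, `[`, "", 3L), default_source),
    concept_id = ifelse(nf >= 4L, vapply(fields, `[`, "", 4L), NA_character_)
  ), stem_keys = stem_keys)
}

#' Write a dictionary to TSV
#'
#' Inverse of [read_dict_tsv()]: reading the written file back yields the
#' same entry set.
#'
#' @param dict An `entity_dictionary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dict_tsv <- function(dict, path) {
  lines <- paste(dict$surface, dict$entity_type, dict$source,
                 ifelse(is.na(dict$concept_id), "", dict$concept_id),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Standard MeSH top-category labels
#'
#' The 16 top-level MeSH tree branches, keyed by the leading letter of a tree
#' number ("C17.300" is a Diseases descriptor).
#'
#' @return Named character vector, letter -> category label.
#' @export
mesh_categories <- function() {
  c(A = "Anatomy", B = "Organisms", C = "Diseases",
    D = "Chemicals and Drugs",
    E = "Analytical, Diagnostic and Therapeutic Techniques and Equipment",
    F = "Psychiatry and Psychology", G = "Phenomena and Processes",
    H = "Disciplines and Occupations",
    I = "Anthropology, Education, Sociology and Social Phenomena",
    J = "Technology, Industry, Agriculture", K = "Humanities",
    L = "Information Science", M = "Named Groups", N = "Health Care",
    V = "Publication Characteristics", Z = "Geographicals")
}

#' Read a MeSH-tree-style term table
#'
#' Two tab-separated columns, term and tree number; the leading letter of the
#' tree number selects the top category, so "Rheumatic Diseases" with tree
#' number "C17.300" becomes an entry typed "Diseases". A term listed under
#' several tree numbers yields one entry per distinct resulting type.
#'
#' @param path File path.
#' @param category_names Named character vector mapping the leading letter to
#'   a category label; defaults to [mesh_categories()].
#' @param source Source name for the resulting entries (default "MeSH").
#' @return An `entity_dictionary`.
#' @export
read_tree_map <- function(path, category_names = mesh_categories(),
                          source = "MeSH") {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(entity_dictionary(NULL))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed tree-map line ", idx[which(nf < 2L)[1]], " in ", path)
  }
  term <- vapply(fields, `[`, "", 1L)
  tree <- vapply(fields, `[`, "", 2L)
  letter <- toupper(substr(trimws(tree), 1L, 1L))
  unknown <- setdiff(unique(letter), names(category_names))
  if (length(unknown)) {
    stop("tree-number category letter not in category_names: ",
         paste(unknown, collapse = ", "))
  }
  entity_dictionary(tibble::tibble(
    surface = term,
    entity_type = unname(category_names[letter]),
    source = source,
    concept_id = tree
  ))
}

#' Merge entity dictionaries
#'
#' Union of entries with provenance preserved: when the same normalized
#' surface carries different types across sources, all entries are kept and
#' the extraction stage disambiguates by source priority.
#'
#' @param dicts List of `entity_dictionary` objects (may be empty).
#' @param priority Ordered source names covering every source present;
#'   defaults to the concatenation of the inputs' priorities.
#' @return An `entity_dictionary`.
#' @examples
#' d1 <- entity_dictionary(data.frame(surface = "EGR-1",
#'   entity_type = "Protein", source = "GENIA"))
#' d2 <- entity_dictionary(data.frame(surface = "Egr 1",
#'   entity_type = "Chemicals and Drugs", source = "MeSH"))
#' merge_dictionaries(list(d1, d2), priority = c("GENIA", "MeSH"))
#' @export
merge_dictionaries <- function(dicts, priority = NULL) {
  stopifnot(is.list(dicts))
  if (!length(dicts)) return(entity_dictionary(NULL, priority))
  all_entries <- dplyr::bind_rows(lapply(dicts, tibble::as_tibble))
  if (is.null(priority)) {
    priority <- unique(unlist(lapply(dicts, source_priority)))
  }
  entity_dictionary(all_entries, source_priority = priority)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
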