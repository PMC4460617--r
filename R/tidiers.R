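#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname spedner-tidiers
#' @param x An object produced by this package.
#' @param ... Unused.
tidy.ner_extraction <- function(x, ...) x$mentions

#' @export
#' @rdname spedner-tidiers
glance.ner_extraction <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    n_mentions = nrow(x$mentions),
    n_short_circuit = sum(tr$event == "short_circuit"),
    n_sped_selected = sum(tr$event == "sped_selected"),
    n_merged_away = sum(tr$event == "merged_away"),
    n_overlap_dropped = sum(tr$event == "overlap_dropped"),
    mode = x$config$mode
  )
}

#' @export
#' @rdname spedner-tidiers
tidy.ner_corpus_extraction <- function(x, ...) x$mentions

#' @export
#' @rdname spedner-tidiers
glance.ner_corpus_extraction <- function(x, ...) {
  tibble::tibble(
    n_passages = nrow(x$passages),
    n_mentions = nrow(x$mentions),
    n_types = length(unique(x$mentions$entity_type)),
    mean_score = if (nrow(x$mentions)) mean(x$mentions$score) else NA_real_,
    mode = x$config$mode
  )
}

#' @export
#' @rdname spedner-tidiers
tidy.synth_corpus <- function(x, ...) x$gold

#' @export
#' @rdname spedner-tidiers
glance.synth_corpus <- function(x, ...) {
  tibble::tibble(
    n_passages = nrow(x$passages),
    n_gold = nrow(x$gold),
    n_variant = sum(!x$gold$surface %in% x$dictionary$surface),
    variant_rate = x$variant_rate,
    seed = x$seed
  )
}

#' Tidiers for spedner result objects
#'
#' [tidy()] returns the row-per-observation view of a result (mentions for
#' extractions, gold mentions for synthetic corpora, per-type metrics for
#' evaluations); [glance()] returns a one-row summary.
#'
#' @name spedner-tidiers
NULL

#' @export
#' @rdname spedner-tidiers
tidy.ner_evaluation <- function(x, ...) x$by_type

#' @export
#' @rdname spedner-tidiers
glance.ner_evaluation <- function(x, ...) x$overall

#' Plot an evaluation
#'
#' Bar chart of precision, recall and F1 per entity type.
#'
#' @param object A `ner_evaluation` from [evaluate_mentions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ner_evaluation <- function(object, ...) {
  d <- object$by_type |>
    tidyr::pivot_longer(cols = c("precision", "recall", "f1"),
                        names_to = "measure", values_to = "value")
  d$measure <- factor(d$measure, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entity_type, y = .data$value,
                                  fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) {
      paste0(100 * v, "%")
    }) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Strict-match scores by entity type") +
    ggplot2::theme_minimal()
}

#' Plot extracted mention spans
#'
#' Segment plot of mention character spans by entity type, shaded by score
#' (0 = exact dictionary hit).
#'
#' @param object A `ner_corpus_extraction` (or `ner_extraction`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ner_corpus_extraction <- function(object, ...) {
  m <- object$mentions
  ggplot2::ggplot(m, ggplot2::aes(x = .data$start, xend = .data$end,
                                  y = .data$passage_id,
                                  yend = .data$passage_id,
                                  colour = .data$score)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$entity_type)) +
    ggplot2::labs(x = "character offset", y = NULL,
                  title = "Extracted mention spans") +
    ggplot2::theme_minimal()
}
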