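#' Strict mention-matching counts
#'
#' One-to-one strict matching: a prediction is a true positive only if some
#' unmatched gold mention agrees exactly on (start, end, entity type) — and
#' on `passage_id` when either table carries one. Unmatched predictions are
#' false positives, unmatched gold mentions false negatives.
#'
#' @param gold,pred Mention tibbles over the same passages.
#' @return One-row tibble with `tp`, `fp`, `fn`.
#' @export
count_matches <- function(gold, pred) {
  gold <- tibble::as_tibble(gold)
  pred <- tibble::as_tibble(pred)
  key <- function(d) {
    pid <- if ("passage_id" %in% names(d)) d$passage_id else ""
    if (!nrow(d)) return(character(0))
    paste(pid, d$start, d$end, d$entity_type, sep = "\r")
  }
  gk <- table(key(gold))
  pk <- table(key(pred))
  shared <- intersect(names(gk), names(pk))
  tp <- if (length(shared)) sum(pmin(gk[shared], pk[shared])) else 0L
  tibble::tibble(tp = as.integer(tp),
                 fp = as.integer(nrow(pred) - tp),
                 fn = as.integer(nrow(gold) - tp))
}

#' Precision, recall and F1 from counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, F1 the harmonic
#' mean of the two; any 0/0 is defined as 0.
#'
#' @param counts One-row data frame with `tp`, `fp`, `fn`
#'   (from [count_matches()]).
#' @return One-row tibble `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
ner_metrics <- function(counts) {
  counts <- tibble::as_tibble(counts)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  dplyr::mutate(counts, precision = p, recall = r,
                f1 = f_measure(p, r))
}

#' F-measure from precision and recall
#'
#' Harmonic mean `2PR / (P + R)` on whatever scale the inputs use
#' (fractions or percentages); 0 when both are 0.
#'
#' @param precision,recall Non-negative numerics (vectorized).
#' @return Numeric vector of F values.
#' @examples
#' f_measure(70.7, 68.9)  # 69.8 after rounding to one decimal
#' @export
f_measure <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Seeded k-fold assignment
#'
#' Shuffles the items with the given seed and deals them round-robin into k
#' folds, so fold sizes differ by at most one; deterministic per seed.
#'
#' @param n_items Number of items (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Tibble with `item` (1..n) and `fold` (1..k).
#' @export
kfold_split <- function(n_items, k, seed) {
  stopifnot(k >= 2L)
  if (n_items < k) stop("n_items (", n_items, ") must be at least k (",
                        k, ")")
  fold <- integer(n_items)
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(n_items)
    fold[ord] <- rep_len(seq_len(k), n_items)
  })
  tibble::tibble(item = seq_len(n_items), fold = fold)
}

.parse_iob_tag <- function(tag, lineno) {
  if (tag == "O") return(c("O", NA_character_))
  if (grepl("^[BI]-.+", tag)) {
    return(c(substr(tag, 1L, 1L), substring(tag, 3L)))
  }
  stop("invalid IOB2 tag at line ", lineno, ": '", tag, "'")
}

#' Read an IOB2-tagged corpus
#'
#' One `token<TAB>tag` pair per line, tags `O` / `B-type` / `I-type`, blank
#' lines separating sentences. Sentence text is reconstructed by joining
#' tokens with single spaces; contiguous B-/I- runs become mentions with
#' 0-based half-open character spans over that text. An `I-` tag without a
#' preceding `B-`/`I-` of the same type is an error naming the line, or is
#' silently repaired to `B-` with `lenient = TRUE`.
#'
#' @param path File path.
#' @param lenient Repair dangling `I-` tags instead of erroring?
#' @return A `ner_corpus` list with `passages` (tibble `passage_id`, `text`)
#'   and `gold` (mention tibble keyed by `passage_id`).
#' @export
read_iob2 <- function(path, lenient = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  # group contiguous non-blank runs into sentences
  grp <- cumsum(blank)
  passages <- list(); gold <- list(); pnum <- 0L
  for (g in unique(grp[!blank])) {
    idx <- which(grp == g & !blank)
    if (!length(idx)) next
    pnum <- pnum + 1L
    pid <- sprintf("p%04d", pnum)
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed IOB2 line ", idx[which(lengths(parts) != 2L)[1]],
           " in ", path)
    }
    toks <- vapply(parts, `[`, "", 1L)
    tags <- vapply(parts, `[`, "", 2L)
    starts <- c(0L, cumsum(nchar(toks) + 1L)[-length(toks)])
    ends <- starts + nchar(toks)
    ms <- list()
    cur <- NULL
    prev_type <- NA_character_
    for (i in seq_along(toks)) {
      tg <- .parse_iob_tag(tags[i], idx[i])
      kind <- tg[1L]; ty <- tg[2L]
      if (kind == "I" && (is.na(prev_type) || prev_type != ty)) {
        if (!lenient) {
          stop("dangling I- tag at line ", idx[i], " in ", path,
               " (no preceding B-", ty, "/I-", ty, ")")
        }
        kind <- "B"
      }
      if (kind != "I" && !is.null(cur)) { ms[[length(ms) + 1L]] <- cur
                                          cur <- NULL }
      if (kind == "B") {
        cur <- list(start = starts[i], end = ends[i], type = ty)
      } else if (kind == "I") {
        cur$end <- ends[i]
      }
      prev_type <- if (kind == "O") NA_character_ else ty
    }
    if (!is.null(cur)) ms[[length(ms) + 1L]] <- cur
    text <- paste(toks, collapse = " ")
    passages[[pnum]] <- tibble::tibble(passage_id = pid, text = text)
    gold[[pnum]] <- if (length(ms)) tibble::tibble(
      passage_id = pid,
      start = vapply(ms, function(x) as.integer(x$start), integer(1)),
      end = vapply(ms, function(x) as.integer(x$end), integer(1)),
      surface = vapply(ms, function(x) substr(text, x$start + 1L, x$end),
                       character(1)),
      entity_type = vapply(ms, function(x) x$type, character(1)))
  }
  structure(list(
    passages = if (length(passages)) dplyr::bind_rows(passages)
               else tibble::tibble(passage_id = character(),
                                   text = character()),
    gold = if (length(gold)) dplyr::bind_rows(gold)
           else tibble::tibble(passage_id = character(), start = integer(),
                               end = integer(), surface = character(),
                               entity_type = character())
  ), class = "ner_corpus")
}

#' Write a corpus in IOB2 format
#'
#' Inverse of [read_iob2()] for passages whose tokens are single-space
#' separated and whose mention boundaries are token-aligned (both hold for
#' [synth_corpus()] output and for anything read by [read_iob2()]):
#' write-then-read reproduces the mention sets exactly and read-then-write
#' reproduces the file byte for byte.
#'
#' @param corpus A list with `passages` and `gold` tibbles (a `synth_corpus`
#'   or `ner_corpus`), or a passages tibble if `mentions` is supplied.
#' @param path Output file path.
#' @param mentions Mention tibble when `corpus` is a plain passages tibble.
#' @return `path`, invisibly.
#' @export
write_iob2 <- function(corpus, path, mentions = NULL) {
  if (is.data.frame(corpus)) {
    passages <- tibble::as_tibble(corpus)
    stopifnot(!is.null(mentions))
  } else {
    passages <- corpus$passages
    mentions <- mentions %||% corpus$gold
  }
  mentions <- tibble::as_tibble(mentions)
  blocks <- character(nrow(passages))
  for (p in seq_len(nrow(passages))) {
    text <- passages$text[p]
    toks <- strsplit(text, " ", fixed = TRUE)[[1]]
    starts <- c(0L, cumsum(nchar(toks) + 1L)[-length(toks)])
    ends <- starts + nchar(toks)
    tags <- rep("O", length(toks))
    pm <- mentions[mentions$passage_id == passages$passage_id[p], ,
                   drop = FALSE]
    pm <- pm[order(pm$start), , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      inside <- which(starts >= pm$start[r] & ends <= pm$end[r])
      if (!length(inside) || starts[inside[1L]] != pm$start[r] ||
          ends[inside[length(inside)]] != pm$end[r]) {
        stop("mention [", pm$start[r], ",", pm$end[r],
             ") is not token-aligned in passage ",
             passages$passage_id[p])
      }
      tags[inside[1L]] <- paste0("B-", pm$entity_type[r])
      if (length(inside) > 1L) {
        tags[inside[-1L]] <- paste0("I-", pm$entity_type[r])
      }
    }
    blocks[p] <- paste(paste(toks, tags, sep = "\t"), collapse = "\n")
  }
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Evaluate predictions against gold mentions
#'
#' Strict-match scoring, overall and per entity type, with optional k-fold
#' aggregation over passages.
#'
#' @param gold,pred Mention tibbles (with `passage_id` when multi-passage).
#' @param k Optional number of folds; when given, passages are split with
#'   [kfold_split()] and per-fold metrics are averaged.
#' @param seed Seed for the fold split (required with `k`).
#' @return A `ner_evaluation`: list with `overall` (one-row metrics),
#'   `by_type` (per-entity-type metrics) and optionally `by_fold`.
#' @export
evaluate_mentions <- function(gold, pred, k = NULL, seed = 1L) {
  gold <- tibble::as_tibble(gold)
  pred <- tibble::as_tibble(pred)
  overall <- ner_metrics(count_matches(gold, pred))
  types <- sort(unique(c(gold$entity_type, pred$entity_type)))
  by_type <- dplyr::bind_rows(lapply(types, function(ty) {
    m <- ner_metrics(count_matches(gold[gold$entity_type == ty, ],
                                   pred[pred$entity_type == ty, ]))
    tibble::add_column(m, entity_type = ty, .before = 1L)
  }))
  by_fold <- NULL
  if (!is.null(k)) {
    stopifnot("passage_id" %in% names(gold),
              "passage_id" %in% names(pred))
    pids <- sort(unique(c(gold$passage_id, pred$passage_id)))
    folds <- kfold_split(length(pids), k, seed)
    by_fold <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
      ids <- pids[folds$fold == f]
      m <- ner_metrics(count_matches(
        gold[gold$passage_id %in% ids, ],
        pred[pred$passage_id %in% ids, ]))
      tibble::add_column(m, fold = f, .before = 1L)
    }))
  }
  structure(list(overall = overall, by_type = by_type, by_fold = by_fold),
            class = "ner_evaluation")
}

#' @export
print.ner_evaluation <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<ner_evaluation> P %.1f%% R %.1f%% F1 %.1f%% (TP %d FP %d FN %d)\n",
    100 * o$precision, 100 * o$recall, 100 * o$f1, o$tp, o$fp, o$fn))
  if (!is.null(x$by_fold)) {
    cat(sprintf("  %d-fold mean F1 %.1f%%\n", nrow(x$by_fold),
                100 * mean(x$by_fold$f1)))
  }
  invisible(x)
}
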