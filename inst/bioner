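#!/usr/bin/env Rscript

# bioner — command-line front end for the spedner package.
# Subcommands: build-dict, extract, synth, eval, sped.

suppressPackageStartupMessages({
  library(spedner)
  library(jsonlite)
})

usage <- function(status = 1L) {
  cat(
"usage:
  bioner build-dict --tsv FILE [--tsv FILE ...] [--tree-map FILE]
                    [--categories FILE] -o DICT.tsv
  bioner extract    --dict DICT.tsv --in FILE(.txt|.jsonl)
                    [--mode all|context|sped|exact] [--config FILE]
                    -o MENTIONS.jsonl
  bioner synth      --dict DICT.tsv --n N [--variant-rate R] [--seed S]
                    -o DIR
  bioner eval       --gold GOLD.iob2 --pred PRED.iob2 [--k K] [--seed S]
  bioner sped       --s STRING --t STRING [--piece-length N] [--gap-cost G]
                    [--prefix-cap K] [--weight-fn eq1|aligned]
", file = if (status == 0) stdout() else stderr())
  quit(status = status)
}

parse_args <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    key <- if (a == "-o") "out" else if (startsWith(a, "--")) substring(a, 3L)
           else stop("unexpected argument: ", a)
    if (i == length(args)) stop("missing value for --", key)
    flags[[key]] <- c(flags[[key]], args[i + 1L])
    i <- i + 2L
  }
  flags
}

need <- function(flags, key) {
  if (is.null(flags[[key]])) stop("missing required option --", key)
  flags[[key]]
}

read_config <- function(path) {
  # plain key = value lines; '#' comments; strings may be quoted
  out <- list()
  for (line in readLines(path, warn = FALSE)) {
    line <- sub("#.*$", "", line)
    if (!grepl("=", line, fixed = TRUE)) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

cli_mode <- function(m) {
  switch(m,
         all = "all",
         context = , context_only = "context_only",
         sped = , sped_only = "sped_only",
         exact = , exact_only = "exact_only",
         stop("unknown mode: ", m))
}

config_from_flags <- function(flags) {
  cfg <- if (!is.null(flags$config)) read_config(flags$config) else list()
  sped <- sped_params(
    piece_length = as.integer(cfg$piece_length %||% 1L),
    gap_cost = cfg$gap_cost %||% 1.0,
    prefix_weight = cfg$prefix_weight %||% 0.1,
    prefix_cap = as.integer(cfg$prefix_cap %||% 4L),
    weight_fn = cfg$weight_fn %||% "eq1")
  pipeline_config(
    mode = cli_mode(flags$mode %||% cfg$mode %||% "all"),
    max_cost = cfg$max_cost %||% 0.6,
    max_span_tokens = as.integer(cfg$max_span_tokens %||% 5L),
    sped = sped,
    sped_accept_threshold = cfg$sped_accept_threshold %||% 0.3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_build_dict <- function(flags) {
  dicts <- lapply(flags$tsv, read_dict_tsv)
  if (!is.null(flags[["tree-map"]])) {
    cats <- mesh_categories()
    if (!is.null(flags$categories)) {
      tab <- read.delim(flags$categories, header = FALSE, sep = "\t",
                        col.names = c("letter", "label"),
                        colClasses = "character")
      cats <- setNames(tab$label, tab$letter)
    }
    dicts <- c(dicts, lapply(flags[["tree-map"]], read_tree_map,
                             category_names = cats))
  }
  if (!length(dicts)) stop("no input dictionaries given")
  write_dict_tsv(merge_dictionaries(dicts), need(flags, "out"))
  invisible(NULL)
}

read_passages <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    recs <- lapply(readLines(path, warn = FALSE), fromJSON)
    data.frame(
      passage_id = vapply(seq_along(recs), function(i) {
        as.character(recs[[i]]$passage_id %||% sprintf("p%04d", i))
      }, ""),
      text = vapply(recs, function(r) as.character(r$text), ""))
  } else {
    lines <- readLines(path, warn = FALSE)
    data.frame(passage_id = sprintf("p%04d", seq_along(lines)),
               text = lines)
  }
}

cmd_extract <- function(flags) {
  dict <- read_dict_tsv(need(flags, "dict"))
  passages <- read_passages(need(flags, "in"))
  cfg <- config_from_flags(flags)
  res <- extract_corpus(passages, dict, cfg)
  m <- res$mentions
  out <- file(need(flags, "out"), "wb")
  on.exit(close(out))
  for (r in seq_len(nrow(m))) {
    writeLines(toJSON(list(
      passage_id = m$passage_id[r], start = m$start[r], end = m$end[r],
      surface = m$surface[r], entity_type = m$entity_type[r],
      score = m$score[r], source = m$source[r]), auto_unbox = TRUE,
      digits = NA), out)
  }
  invisible(NULL)
}

cmd_synth <- function(flags) {
  dict <- read_dict_tsv(need(flags, "dict"))
  corpus <- synth_corpus(dict,
                         n_passages = as.integer(need(flags, "n")),
                         variant_rate = as.numeric(flags[["variant-rate"]]
                                                   %||% 0),
                         seed = as.integer(flags$seed %||% 1L))
  dir.create(need(flags, "out"), showWarnings = FALSE, recursive = TRUE)
  p <- corpus$passages
  writeLines(paste(p$passage_id, p$text, sep = "\t"),
             file.path(flags$out, "passages.tsv"), useBytes = TRUE)
  g <- corpus$gold
  writeLines(paste(g$passage_id, g$start, g$end, g$surface, g$entity_type,
                   sep = "\t"),
             file.path(flags$out, "gold.tsv"), useBytes = TRUE)
  write_iob2(corpus, file.path(flags$out, "gold.iob2"))
  invisible(NULL)
}

cmd_eval <- function(flags) {
  gold <- read_iob2(need(flags, "gold"))
  pred <- read_iob2(need(flags, "pred"))
  k <- if (!is.null(flags$k)) as.integer(flags$k) else NULL
  ev <- evaluate_mentions(gold$gold, pred$gold, k = k,
                          seed = as.integer(flags$seed %||% 1L))
  o <- ev$overall
  cat(sprintf("precision %.1f%%  recall %.1f%%  f1 %.1f%%\n",
              100 * o$precision, 100 * o$recall, 100 * o$f1))
  cat(sprintf("tp %d  fp %d  fn %d\n", o$tp, o$fp, o$fn))
  if (!is.null(ev$by_fold)) {
    cat(sprintf("%d-fold means: precision %.1f%%  recall %.1f%%  f1 %.1f%%\n",
                k, 100 * mean(ev$by_fold$precision),
                100 * mean(ev$by_fold$recall), 100 * mean(ev$by_fold$f1)))
  }
  invisible(NULL)
}

cmd_sped <- function(flags) {
  params <- sped_params(
    piece_length = as.integer(flags[["piece-length"]] %||% 1L),
    gap_cost = as.numeric(flags[["gap-cost"]] %||% 1.0),
    prefix_cap = as.integer(flags[["prefix-cap"]] %||% 4L),
    weight_fn = flags[["weight-fn"]] %||% "eq1")
  cat(sprintf("%.6f\n", sped_distance(need(flags, "s"), need(flags, "t"),
                                      params)))
  invisible(NULL)
}

main <- function() {
  argv <- commandArgs(trailingOnly = TRUE)
  if (!length(argv)) usage()
  cmd <- argv[1]
  if (cmd %in% c("-h", "--help", "help")) usage(0L)
  flags <- parse_args(argv[-1])
  switch(cmd,
         "build-dict" = cmd_build_dict(flags),
         "extract" = cmd_extract(flags),
         "synth" = cmd_synth(flags),
         "eval" = cmd_eval(flags),
         "sped" = cmd_sped(flags),
         { cat("unknown subcommand: ", cmd, "\n", sep = "", file = stderr())
           usage() })
}

main()
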