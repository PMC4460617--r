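#' Tokenize a passage
#'
#' Splits on whitespace and detaches leading/trailing punctuation characters
#' of each chunk as separate single-character tokens, so `"E coli."` yields
#' `"E"`, `"coli"`, `"."`. Internal punctuation (the hyphen of `"EGR-1"`)
#' stays inside its token. Offsets are 0-based character positions; slicing
#' the passage at `[start, start + nchar(text))` reproduces each token.
#'
#' @param text Passage text.
#' @return Tibble with `text`, `start` and an (unfilled) `pos` column.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  out <- tibble::tibble(text = character(), start = integer(),
                        pos = NA_character_)
  if (is.na(text) || !nzchar(text)) return(out)
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  toks <- list()
  for (i in seq_along(starts)) {
    chunk <- substr(text, starts[i] + 1L, starts[i] + lens[i])
    s <- starts[i]
    # peel leading punctuation
    while (nchar(chunk) > 1L && grepl("^[[:punct:]]", chunk)) {
      toks[[length(toks) + 1L]] <- c(substr(chunk, 1L, 1L), s)
      chunk <- substring(chunk, 2L)
      s <- s + 1L
    }
    # peel trailing punctuation
    trail <- character(0)
    while (nchar(chunk) > 1L && grepl("[[:punct:]]$", chunk)) {
      trail <- c(substr(chunk, nchar(chunk), nchar(chunk)), trail)
      chunk <- substr(chunk, 1L, nchar(chunk) - 1L)
    }
    toks[[length(toks) + 1L]] <- c(chunk, s)
    if (length(trail)) {
      for (k in seq_along(trail)) {
        toks[[length(toks) + 1L]] <- c(trail[k], s + nchar(chunk) + k - 1L)
      }
    }
  }
  tibble::tibble(
    text = vapply(toks, `[`, "", 1L),
    start = as.integer(vapply(toks, `[`, "", 2L)),
    pos = NA_character_
  )
}

.pos_tags <- c("NOUN", "ADJ", "VERB", "NUM", "OTHER")

.closed_class <- c(
  "the", "a", "an", "of", "in", "on", "at", "by", "for", "with", "to",
  "from", "and", "or", "but", "as", "that", "this", "these", "those", "it",
  "its", "we", "they", "not", "no", "than", "then", "there", "which", "who",
  "whose", "what", "when", "where", "while", "if", "because", "however",
  "thus", "also", "both", "each", "between", "during", "after", "before",
  "via", "per", "their", "our", "all", "some", "any", "most", "more", "less",
  "such", "into", "within", "under", "over", "upon", "among", "through")

.verb_words <- c(
  "be", "is", "are", "was", "were", "been", "being", "am", "has", "have",
  "had", "having", "do", "does", "did", "done", "can", "could", "may",
  "might", "must", "shall", "should", "will", "would", "show", "shows",
  "showed", "shown", "observe", "observed", "observes", "measure",
  "measured", "measures", "induce", "induced", "induces", "express",
  "expressed", "expresses", "inhibit", "inhibited", "inhibits", "activate",
  "activated", "activates", "increase", "increased", "increases", "decrease",
  "decreased", "decreases", "suggest", "suggests", "suggested", "indicate",
  "indicates", "indicated", "find", "found", "report", "reported",
  "demonstrate", "demonstrated", "detect", "detected", "perform",
  "performed", "analyze", "analyzed", "examine", "examined", "treat",
  "treated", "compare", "compared", "bind", "binds", "bound", "regulate",
  "regulated", "regulates", "encode", "encodes", "encoded", "contain",
  "contains", "contained", "remain", "remains", "remained", "reveal",
  "revealed", "require", "required", "requires", "involve", "involved",
  "involves", "produce", "produced", "produces")

.spedner_cache <- new.env(parent = emptyenv())

.verb_stems <- function() {
  if (is.null(.spedner_cache$verb_stems)) {
    .spedner_cache$verb_stems <- unique(porter_stem(.verb_words))
  }
  .spedner_cache$verb_stems
}

#' Default rule-based POS tagger
#'
#' Deterministic tagger over `{NOUN, ADJ, VERB, NUM, OTHER}` needing no
#' trained model: closed-class function words tag OTHER, a verb word list
#' (plus `-ing`/`-ed` forms sharing a stem with it) tags VERB, digit-initial
#' tokens tag NUM, `-ly` adverbs and punctuation tag OTHER, common adjectival
#' suffixes tag ADJ, and everything else defaults to NOUN, which is the
#' right default for biomedical term tokens.
#'
#' @param words Character vector of token texts.
#' @return Character vector of tags.
#' @export
default_pos_tagger <- function(words) {
  w <- tolower(words)
  tag <- rep("NOUN", length(w))
  tag[grepl("^[[:punct:]]+$", w)] <- "OTHER"
  tag[grepl("^[0-9]", w)] <- "NUM"
  tag[w %in% .closed_class] <- "OTHER"
  tag[w %in% .verb_words] <- "VERB"
  isly <- grepl("ly$", w) & tag == "NOUN"
  tag[isly] <- "OTHER"
  infl <- grepl("(ing|ed)$", w) & tag == "NOUN"
  tag[infl][porter_stem(w[infl]) %in% .verb_stems()] <- "VERB"
  adj <- tag == "NOUN" & grepl("(ous|ive|able|ible|ic|al)$", w) &
    nchar(w) > 4L
  tag[adj] <- "ADJ"
  tag
}

#' Tag tokens with parts of speech
#'
#' Fills the `pos` column of a [tokenize()] tibble. Any tagger honoring the
#' contract (character vector of token texts in, tags from
#' `{NOUN, ADJ, VERB, NUM, OTHER}` out, one per token) may be injected.
#'
#' @param tokens Token tibble from [tokenize()].
#' @param tagger Tagging function; default [default_pos_tagger()].
#' @return The token tibble with `pos` filled.
#' @export
pos_tag <- function(tokens, tagger = default_pos_tagger) {
  stopifnot(is.data.frame(tokens), is.function(tagger))
  if (!nrow(tokens)) return(tokens)
  tags <- tagger(tokens$text)
  if (length(tags) != nrow(tokens) || !all(tags %in% .pos_tags)) {
    stop("tagger must return one tag per token from {",
         paste(.pos_tags, collapse = ", "), "}")
  }
  tokens$pos <- tags
  tokens
}

.mention_tokens <- function(tokens, start, end, within = TRUE) {
  tstart <- tokens$start
  tend <- tokens$start + nchar(tokens$text)
  if (within) {
    tokens[tstart >= start & tend <= end, , drop = FALSE]
  } else {
    tokens[tstart < end & tend > start, , drop = FALSE]
  }
}

#' Merge overlapping candidate mentions
#'
#' Resolves nested candidate mentions: the shorter mention is absorbed into
#' the longer one when (1) both start at the same character, (2) they carry
#' the same entity type, (3) every token overlapping either mention is
#' nominal (NOUN, or ADJ/NUM inside a noun phrase), and (4) the shorter
#' mention's stemmed token sequence is a prefix of the longer's. Applied to
#' a fixed point; the survivors are returned sorted by (start, descending
#' length). The output is always a subset of the input.
#'
#' @param mentions Mention tibble (`start`, `end`, `surface`, `entity_type`,
#'   optionally `score` and more), all over the same passage as `tokens`.
#' @param tokens POS-tagged token tibble of the passage ([pos_tag()]).
#' @param pure_noun Require plain NOUN tokens only (drop the ADJ/NUM
#'   allowance)? Default `FALSE`.
#' @return The merged mention tibble.
#' @export
merge_mentions <- function(mentions, tokens, pure_noun = FALSE) {
  stopifnot(is.data.frame(mentions), is.data.frame(tokens))
  if (!nrow(mentions)) return(tibble::as_tibble(mentions))
  mentions <- tibble::as_tibble(mentions)
  allowed <- if (pure_noun) "NOUN" else c("NOUN", "ADJ", "NUM")
  stems <- function(start, end) {
    mt <- .mention_tokens(tokens, start, end, within = TRUE)
    porter_stem(tolower(mt$text))
  }
  nominal <- function(start, end) {
    ov <- .mention_tokens(tokens, start, end, within = FALSE)
    nrow(ov) > 0L && all(ov$pos %in% allowed)
  }
  repeat {
    n <- nrow(mentions)
    drop <- rep(FALSE, n)
    len <- mentions$end - mentions$start
    for (i in seq_len(n)) {
      if (drop[i]) next
      for (j in seq_len(n)) {
        if (i == j || drop[j] || drop[i]) next
        # i shorter, j longer, same start and type
        if (mentions$start[i] != mentions$start[j]) next
        if (len[i] >= len[j]) next
        if (mentions$entity_type[i] != mentions$entity_type[j]) next
        span_end <- max(mentions$end[i], mentions$end[j])
        if (!nominal(mentions$start[i], span_end)) next
        si <- stems(mentions$start[i], mentions$end[i])
        sj <- stems(mentions$start[j], mentions$end[j])
        if (length(si) <= length(sj) &&
            identical(si, sj[seq_along(si)])) {
          drop[i] <- TRUE
        }
      }
    }
    if (!any(drop)) break
    mentions <- mentions[!drop, , drop = FALSE]
  }
  mentions[order(mentions$start, -(mentions$end - mentions$start)), ]
}
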