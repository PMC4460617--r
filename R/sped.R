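#' SPED parameters
#'
#' Tunables of the Shortest Path Edit Distance. `piece_length` is the length
#' L into which both strings are cut (the last piece absorbs the remainder);
#' `gap_cost` weights the horizontal (deletion) and vertical (insertion)
#' edges of the alignment graph and can be fitted with [tune_gap_cost()];
#' `prefix_weight` and `prefix_cap` drive the common-prefix re-scorer, with
#' the cap following the Jaro-Winkler convention of at most 4 prefix
#' characters; `weight_fn` selects the box-score: `"eq1"` averages the
#' mismatch indicator over *all* character pairs of the two pieces, while
#' `"aligned"` averages over aligned positions only (identical for L = 1).
#'
#' @param piece_length Piece length L (integer >= 1). Default 1 makes SPED a
#'   normalized grid edit distance.
#' @param gap_cost Gap edge weight (>= 0). Default 1.
#' @param prefix_weight Per-prefix-character rescoring weight in `[0, 1]`.
#' @param prefix_cap Maximum prefix length credited (>= 0). Default 4.
#' @param weight_fn `"eq1"` or `"aligned"`.
#' @return A `sped_params` list.
#' @export
sped_params <- function(piece_length = 1L, gap_cost = 1.0,
                        prefix_weight = 0.1, prefix_cap = 4L,
                        weight_fn = c("eq1", "aligned")) {
  weight_fn <- match.arg(weight_fn)
  stopifnot(piece_length >= 1L, gap_cost >= 0,
            prefix_weight >= 0, prefix_weight <= 1, prefix_cap >= 0)
  structure(list(piece_length = as.integer(piece_length),
                 gap_cost = gap_cost, prefix_weight = prefix_weight,
                 prefix_cap = as.integer(prefix_cap), weight_fn = weight_fn),
            class = "sped_params")
}

#' Partition a string into length-L pieces
#'
#' All pieces have length L except the last, which absorbs the remainder and
#' so has length in `[L, 2L - 1]`; a non-empty string shorter than L is a
#' single piece; the empty string yields no pieces. Piece concatenation
#' always reproduces the input.
#'
#' @param s String to cut.
#' @param L Piece length (>= 1).
#' @return Character vector of pieces.
#' @examples
#' partition_string("abcde", 2)  # "ab" "cde"
#' @export
partition_string <- function(s, L) {
  stopifnot(length(s) == 1L, L >= 1L)
  n <- nchar(s)
  if (n == 0L) return(character(0))
  k <- max(1L, n %/% L)
  starts <- (seq_len(k) - 1L) * L + 1L
  ends <- c(starts[-1L] - 1L, n)
  substring(s, starts, ends)
}

#' Box score of a piece pair
#'
#' Mean pairwise character mismatch over all `|u| * |v|` character pairs of
#' the two pieces (0 for equal characters, 1 otherwise); always in `[0, 1]`
#' and symmetric. Note that for multi-character pieces even identical pieces
#' score above 0 unless they are runs of a single character; this is the
#' printed definition and is kept as the default. For pieces of unequal
#' length the sum runs over all `|u| * |v|` pairs and is divided by
#' `|u| * |v|`.
#'
#' @param u,v Non-empty pieces.
#' @return Mismatch score in `[0, 1]`.
#' @examples
#' box_score("ab", "ab")  # 0.5: pairs (a,a) (a,b) (b,a) (b,b)
#' @export
box_score <- function(u, v) {
  stopifnot(nzchar(u), nzchar(v))
  a <- strsplit(u, "", fixed = TRUE)[[1]]
  b <- strsplit(v, "", fixed = TRUE)[[1]]
  mean(outer(a, b, "!="))
}

#' Aligned-position box score
#'
#' Variant box weight: mismatches are counted at aligned positions only and
#' unmatched overhang positions count as mismatches, the total divided by
#' `max(|u|, |v|)`. Identical pieces score 0.
#'
#' @inheritParams box_score
#' @return Mismatch score in `[0, 1]`.
#' @export
box_score_aligned <- function(u, v) {
  stopifnot(nzchar(u), nzchar(v))
  a <- strsplit(u, "", fixed = TRUE)[[1]]
  b <- strsplit(v, "", fixed = TRUE)[[1]]
  k <- min(length(a), length(b))
  (sum(a[seq_len(k)] != b[seq_len(k)]) + abs(length(a) - length(b))) /
    max(length(a), length(b))
}

.box_weight_fn <- function(name) {
  switch(name, eq1 = box_score, aligned = box_score_aligned,
         stop("unknown weight_fn: ", name))
}

#' Build the alignment lattice of two strings
#'
#' Cuts `s` and `t` into pieces and scores every piece pair with the chosen
#' box weight. `s` runs along the columns (top side), `t` along the rows
#' (left side), so `scores[i, j]` weighs t-piece i against s-piece j.
#'
#' @param s,t Non-empty strings.
#' @param params [sped_params()].
#' @return A `box_lattice`: list of `s_pieces`, `t_pieces`, `scores`.
#' @export
build_lattice <- function(s, t, params = sped_params()) {
  stopifnot(nzchar(s), nzchar(t))
  sp <- partition_string(s, params$piece_length)
  tp <- partition_string(t, params$piece_length)
  fn <- .box_weight_fn(params$weight_fn)
  scores <- outer(seq_along(tp), seq_along(sp),
                  Vectorize(function(i, j) fn(tp[i], sp[j])))
  structure(list(s_pieces = sp, t_pieces = tp,
                 scores = matrix(scores, nrow = length(tp))),
            class = "box_lattice")
}

#' Alignment graph of a lattice
#'
#' Converts each lattice cell to a vertex of a weighted DAG: diagonal edges
#' into `(i, j)` carry the box score `x_ij` (substitution/match), horizontal
#' and vertical edges carry the gap cost (deletion/insertion), and a source
#' vertex connects to `(1, 1)` by a diagonal edge of weight `x_11`. The
#' destination is the bottom-right vertex.
#'
#' @param lattice A [build_lattice()] result.
#' @param gap_cost Gap edge weight (>= 0).
#' @return An `alignment_graph` with `scores`, `gap_cost` and an `edges`
#'   tibble (`from`, `to`, `weight`, `move`).
#' @export
build_graph <- function(lattice, gap_cost = 1.0) {
  stopifnot(inherits(lattice, "box_lattice"), gap_cost >= 0)
  sc <- lattice$scores
  m <- nrow(sc); n <- ncol(sc)
  node <- function(i, j) {
    if (!length(i)) return(character(0))
    paste0("(", i, ",", j, ")")
  }
  from <- "source"; to <- node(1, 1); weight <- sc[1, 1]; move <- "diagonal"
  ij <- expand.grid(i = seq_len(m), j = seq_len(n))
  diag_ok <- ij$i > 1 & ij$j > 1
  from <- c(from, node(ij$i[diag_ok] - 1L, ij$j[diag_ok] - 1L),
            node(ij$i[ij$j > 1], ij$j[ij$j > 1] - 1L),
            node(ij$i[ij$i > 1] - 1L, ij$j[ij$i > 1]))
  to <- c(to, node(ij$i[diag_ok], ij$j[diag_ok]),
          node(ij$i[ij$j > 1], ij$j[ij$j > 1]),
          node(ij$i[ij$i > 1], ij$j[ij$i > 1]))
  weight <- c(weight, sc[cbind(ij$i[diag_ok], ij$j[diag_ok])],
              rep(gap_cost, sum(ij$j > 1) + sum(ij$i > 1)))
  move <- c(move, rep("diagonal", sum(diag_ok)),
            rep("horizontal", sum(ij$j > 1)),
            rep("vertical", sum(ij$i > 1)))
  structure(list(scores = sc, gap_cost = gap_cost,
                 nodes = c("source", as.vector(outer(seq_len(m), seq_len(n),
                                                     node))),
                 edges = tibble::tibble(from = from, to = to,
                                        weight = weight, move = move)),
            class = "alignment_graph")
}

#' Shortest source-to-destination path of an alignment graph
#'
#' Exact DAG shortest path by relaxation in topological (row-major) order.
#' Among minimum-weight paths the one traversing the most edges is reported,
#' which minimizes the edge-normalized score.
#'
#' @param graph A [build_graph()] result.
#' @return A `sped_path` list: `weight`, `edge_count`, `normalized`
#'   (= weight / edge_count).
#' @export
shortest_path <- function(graph) {
  stopifnot(inherits(graph, "alignment_graph"))
  res <- .grid_shortest_path_cpp(graph$scores, graph$gap_cost)
  structure(res, class = "sped_path")
}

#' @export
print.sped_path <- function(x, ...) {
  cat("<sped_path> weight ", format(x$weight), " over ", x$edge_count,
      " edges; normalized ", format(x$normalized), "\n", sep = "")
  invisible(x)
}

#' Length of the common character prefix
#'
#' Measured on the exact strings given (no internal re-normalization).
#'
#' @param s,t Strings.
#' @return Integer prefix length.
#' @export
common_prefix_length <- function(s, t) {
  a <- strsplit(as.character(s), "", fixed = TRUE)[[1]]
  b <- strsplit(as.character(t), "", fixed = TRUE)[[1]]
  k <- min(length(a), length(b))
  if (k == 0L) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (!length(neq)) k else neq[1L] - 1L
}

#' Common-prefix re-scorer
#'
#' Adjusts a normalized shortest-path score downward when the two strings
#' share a prefix: `score - min(prefix, cap) * w * (1 - score)`, clamped to
#' `[0, 1]`. Mirrors the Jaro-Winkler prefix boost, on a distance scale. The
#' result never exceeds the input score.
#'
#' @param sped_norm Normalized path score (>= 0).
#' @param prefix_len Common prefix length (>= 0).
#' @param params [sped_params()] supplying `prefix_weight` and `prefix_cap`.
#' @return Re-scored distance in `[0, 1]`.
#' @examples
#' prefix_rescore(0.5, 2)  # 0.4
#' @export
prefix_rescore <- function(sped_norm, prefix_len, params = sped_params()) {
  stopifnot(sped_norm >= 0, prefix_len >= 0)
  p <- min(as.integer(prefix_len), params$prefix_cap)
  out <- sped_norm - p * params$prefix_weight * (1 - sped_norm)
  min(max(out, 0), 1)
}

# fast internal path: lattice scores without the tibble plumbing
.sped_norm_score <- function(s, t, params) {
  L <- params$piece_length
  sp <- partition_string(s, L)
  tp <- partition_string(t, L)
  if (L == 1L && params$weight_fn == "eq1" &&
      nchar(s) %% L == 0L && nchar(t) %% L == 0L) {
    scores <- outer(tp, sp, "!=") * 1.0
  } else {
    fn <- .box_weight_fn(params$weight_fn)
    scores <- matrix(0, nrow = length(tp), ncol = length(sp))
    for (i in seq_along(tp)) for (j in seq_along(sp)) {
      scores[i, j] <- fn(tp[i], sp[j])
    }
  }
  .grid_shortest_path_cpp(scores, params$gap_cost)
}

#' Shortest Path Edit Distance between two strings
#'
#' The full SPED pipeline: partition both strings into length-L pieces,
#' score all piece pairs, take the edge-normalized shortest path through the
#' alignment DAG, and apply the common-prefix re-scorer. 0 means identical
#' (under L = 1), larger means more dissimilar; with the default box weight
#' and `gap_cost <= 1` the result lies in `[0, 1]`. Two empty strings score
#' 0; exactly one empty string scores 1.
#'
#' @param s,t Strings.
#' @param params [sped_params()].
#' @param prefix_length Optional prefix-length override, e.g. to credit the
#'   common prefix of the *raw* surface forms while scoring normalized forms.
#'   Default: measured on `s` and `t` themselves.
#' @return Distance in `[0, 1]`.
#' @examples
#' sped_distance("ab", "ba")        # 1
#' sped_distance("EGR 1", "EGR-1")  # small: one cheap box on the diagonal
#' @export
sped_distance <- function(s, t, params = sped_params(),
                          prefix_length = NULL) {
  s <- as.character(s); t <- as.character(t)
  if (!nzchar(s) && !nzchar(t)) return(0)
  if (!nzchar(s) || !nzchar(t)) return(1)
  res <- .sped_norm_score(s, t, params)
  p <- prefix_length %||% common_prefix_length(s, t)
  prefix_rescore(res$normalized, p, params)
}

#' Fit the gap cost on labelled string pairs
#'
#' Grid search for the "learning phase" of the gap cost: picks the grid
#' value maximizing the separation between classes, i.e. mean SPED over
#' non-matching pairs minus mean SPED over matching pairs (an empty class
#' contributes 0). Ties go to the smallest grid value.
#'
#' @param pairs Data frame with columns `s`, `t`, `is_match` (logical).
#' @param grid Non-empty numeric vector of candidate gap costs (>= 0).
#' @param params [sped_params()]; its `gap_cost` is overridden per grid
#'   value.
#' @return The selected gap cost.
#' @export
tune_gap_cost <- function(pairs, grid, params = sped_params()) {
  stopifnot(is.numeric(grid), length(grid) > 0, all(grid >= 0))
  pairs <- tibble::as_tibble(pairs)
  objective <- vapply(grid, function(g) {
    p <- params
    p$gap_cost <- g
    d <- mapply(sped_distance, pairs$s, pairs$t,
                MoreArgs = list(params = p), USE.NAMES = FALSE)
    mmatch <- if (any(pairs$is_match)) mean(d[pairs$is_match]) else 0
    mnon <- if (any(!pairs$is_match)) mean(d[!pairs$is_match]) else 0
    mnon - mmatch
  }, numeric(1))
  best <- which(objective >= max(objective) - 1e-12)
  min(grid[best])
}
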