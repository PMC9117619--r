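#' Score anchors over the neighborhood graph
#'
#' Dynamic programming over anchors sorted by (chrom, ref_pos, read_pos):
#' each anchor's score is the best predecessor score plus a constant edge
#' reward `alpha`, or 0 if no admissible predecessor exists. Because the
#' reward does not depend on the inter-anchor distance, a chain crossing a
#' large insertion, deletion, or error-dense stretch scores exactly the
#' same as a tight chain with the same number of anchors — this is what
#' lets the skeleton span structural variants. The graph is never
#' materialised; admissible predecessors are enumerated by a bounded
#' backward scan over the sorted anchors, which yields results identical
#' to an explicit edge list.
#'
#' Ties among equal-score predecessors resolve to the nearest one
#' (largest ref_pos, then largest read_pos), keeping downstream gap
#' alignment cheap and the result deterministic.
#'
#' @param anchors Anchor tibble from [extract_anchors()] (must be sorted
#'   as produced there).
#' @param d Distance bound from [compute_d()].
#' @param alpha Constant edge reward (default 1).
#' @return The input tibble with columns `score` and `prec` (row index of
#'   the best predecessor, `NA` if none) appended.
#' @export
chain_scores <- function(anchors, d, alpha = 1) {
  if (nrow(anchors) == 0L)
    return(dplyr::mutate(anchors, score = numeric(0), prec = integer(0)))
  dp <- chain_dp_cpp(as.integer(anchors$chrom), as.integer(anchors$ref_pos),
                     as.integer(anchors$read_pos), d, alpha)
  dplyr::mutate(anchors, score = dp$score,
                prec = ifelse(dp$prec == 0L, NA_integer_, dp$prec))
}

#' Backtrack the initial alignment skeleton
#'
#' The highest-scoring anchor is the skeleton's end vertex; following best
#' predecessors back to a zero-score anchor (one with no predecessor) and
#' reversing gives the initial skeleton. Ties for the maximum score break
#' to the smallest ref_pos (then read_pos) for determinism.
#'
#' @param dp Scored anchor tibble from [chain_scores()].
#' @return Tibble of skeleton anchors in forward order (possibly a single
#'   anchor); zero rows if `dp` is empty.
#' @export
backtrack_skeleton <- function(dp) {
  if (nrow(dp) == 0L) return(dp[0, setdiff(names(dp), c("score", "prec"))])
  best <- max(dp$score)
  cand <- which(dp$score == best)
  # rows are sorted by (chrom, ref_pos, read_pos); first candidate has the
  # smallest ref_pos among maxima
  v <- cand[1L]
  path <- integer(0)
  while (!is.na(v)) {
    path <- c(v, path)
    v <- dp$prec[v]
  }
  dp[path, , drop = FALSE]
}

#' Refine the skeleton to its densest reference window
#'
#' Among all contiguous sub-paths of the skeleton whose reference extent
#' (difference of anchor start positions) is smaller than `window_l`, the
#' one with the largest score increase is kept. With the constant edge
#' reward this is the sub-path with the most anchors inside the window,
#' found by a two-pointer sweep; ties resolve to the earliest window.
#' Pruning to one read-length window discards stray anchors picked up far
#' from the true locus by chance k-mer hits.
#'
#' @param skel Skeleton tibble from [backtrack_skeleton()] (carrying its
#'   `score` column).
#' @param window_l Window length in reference bases; defaults to the read
#'   length in the mapper.
#' @return The refined contiguous sub-path, same columns as `skel`, with
#'   attribute `increased_score` (score gain across the kept window).
#' @export
refine_skeleton <- function(skel, window_l) {
  stopifnot(window_l >= 1)
  n <- nrow(skel)
  if (n <= 1L) {
    attr(skel, "increased_score") <- 0
    return(skel)
  }
  best_j <- 1L; best_i <- 1L; best_gain <- -Inf
  i <- 1L
  for (j in seq_len(n)) {
    if (i < j) i <- j
    while (i < n && skel$ref_pos[i + 1L] - skel$ref_pos[j] < window_l)
      i <- i + 1L
    gain <- skel$score[i] - skel$score[j]
    if (gain > best_gain) { best_gain <- gain; best_j <- j; best_i <- i }
  }
  out <- skel[best_j:best_i, , drop = FALSE]
  attr(out, "increased_score") <- best_gain
  out
}
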