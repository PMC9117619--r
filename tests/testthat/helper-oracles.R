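# Independent oracles used across the suite. All are deliberately naive
# (plain R, no banding, explicit enumeration) so they share no code path
# with the implementation they check.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Plain full-matrix alignment DP with per-base linear gap cost.
# mode "global": ends fixed at both corners.
# mode "semi":   leading and trailing target gaps free.
# mode "extend": trailing target gap free only.
oracle_align_score <- function(query, target, mode = "global",
                               match = 1, mismatch = -1, gap = -1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  m <- length(q); n <- length(t)
  dp <- matrix(-Inf, m + 1, n + 1)
  dp[1, ] <- if (mode %in% c("semi")) 0 else gap * (0:n)
  dp[, 1] <- gap * (0:m)
  dp[1, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (q[i] == t[j]) match else mismatch
      dp[i + 1, j + 1] <- max(dp[i, j] + s, dp[i, j + 1] + gap,
                              dp[i + 1, j] + gap)
    }
  }
  if (mode == "global") dp[m + 1, n + 1] else max(dp[m + 1, ])
}

# Truly exhaustive recursive enumeration of all alignments (tiny inputs
# only): a cross-check on the DP oracle itself and the implementation.
oracle_align_recursive <- function(query, target, mode = "global",
                                   match = 1, mismatch = -1, gap = -1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  rec <- function(i, j) {
    if (i > length(q)) {
      rest <- length(t) - j + 1
      return(if (mode %in% c("semi", "extend")) 0 else gap * rest)
    }
    if (j > length(t)) return(gap * (length(q) - i + 1))
    best <- rec(i + 1, j + 1) + (if (q[i] == t[j]) match else mismatch)
    best <- max(best, rec(i + 1, j) + gap, rec(i, j + 1) + gap)
    best
  }
  starts <- if (mode == "semi") 0:length(t) else 0
  max(vapply(starts, function(s) rec(1, s + 1), numeric(1)))
}

# Exhaustive longest-path search over the explicit anchor DAG: score of
# the best chain is alpha * (edges on the best path).
oracle_chain_best <- function(anchors, d, alpha = 1) {
  n <- nrow(anchors)
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    edge[i, j] <- skelmap::is_edge(anchors[i, ], anchors[j, ], d)
  best <- 0
  longest_from <- function(v, depth) {
    best <<- max(best, depth)
    for (w in which(edge[v, ])) longest_from(w, depth + 1)
  }
  for (v in seq_len(n)) longest_from(v, 0)
  best * alpha
}

# Brute-force refinement: every contiguous (j, i) sub-path with reference
# extent < window_l; maximise the score increase, ties to earliest j then
# largest i.
oracle_refine <- function(skel, window_l) {
  n <- nrow(skel)
  best <- c(gain = -Inf, j = 1, i = 1)
  for (j in seq_len(n)) for (i in j:n) {
    if (skel$ref_pos[i] - skel$ref_pos[j] >= window_l) next
    gain <- skel$score[i] - skel$score[j]
    if (gain > best["gain"]) best <- c(gain = gain, j = j, i = i)
  }
  skel[best["j"]:best["i"], , drop = FALSE]
}

# Fixed toy anchor set generator for property tests.
random_anchors <- function(n, ref_span = 300, read_span = 300) {
  tb <- tibble::tibble(
    chrom = 1L,
    ref_pos = sort(sample.int(ref_span, n, replace = TRUE)) - 1L,
    read_pos = sample.int(read_span, n, replace = TRUE) - 1L,
    length = 15L)
  tb <- dplyr::distinct(tb)
  dplyr::arrange(tb, chrom, ref_pos, read_pos)
}

# Naive k-mer scan: every offset where the genome substring equals kmer.
naive_kmer_scan <- function(seq, kmer) {
  k <- nchar(kmer)
  starts <- seq_len(nchar(seq) - k + 1)
  starts[vapply(starts, function(s)
    substring(seq, s, s + k - 1) == kmer, logical(1))] - 1L
}

sim_bundle <- function(genome_len, n_reads, len_range, profile, seed) {
  g <- skelmap::generate_genome(genome_len, seed = seed)
  idx <- skelmap::build_index(g)
  sim <- skelmap::simulate_reads(g, n_reads, len_range, profile,
                                 seed = seed + 1L)
  list(genome = g, index = idx, reads = sim$reads, truth = sim$truth)
}
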