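#' Alignment scoring parameters
#'
#' Match +1, mismatch -1, and linear gap costs: with gap open and extend
#' both -1 the usual affine run cost `open + (g-1)*extend` degenerates to
#' -1 per gap base, which is how the fill DPs score gaps. `mu` is the gap
#' classification threshold: a gap pair is a deletion (insertion)
#' candidate when the reference (read) segment is more than `(1+mu)` times
#' the length of the other. `band` bounds the DP corridor half-width.
#'
#' @param mu Gap category threshold (default 2).
#' @param match_score,mismatch_pen,gap_open,gap_extend Per-base scores.
#' @param band_min,band_pad Corridor half-width is
#'   `max(band_min, |length difference| + band_pad)`.
#' @return List of class `aln_params`.
#' @export
aln_params <- function(mu = 2, match_score = 1, mismatch_pen = -1,
                       gap_open = -1, gap_extend = -1,
                       band_min = 32L, band_pad = 64L) {
  stopifnot(mu > 0)
  structure(list(mu = mu, match_score = match_score,
                 mismatch_pen = mismatch_pen, gap_open = gap_open,
                 gap_extend = gap_extend, band_min = as.integer(band_min),
                 band_pad = as.integer(band_pad)),
            class = "aln_params")
}

band_for <- function(params, nq, nt) {
  max(params$band_min, abs(nq - nt) + params$band_pad)
}

empty_fragment <- function() list(ops = integer(0), lens = integer(0), score = 0)

#' Global (Needleman–Wunsch) alignment of two segments
#'
#' End-to-end alignment under [aln_params()] scoring with linear gaps;
#' used to fill match-category gaps. Either sequence may be empty, in
#' which case the result is all-I (empty target) or all-D (empty query).
#'
#' @param query,target Nucleotide strings; `query` is the read side (its
#'   consumed bases become M/I), `target` the reference side (M/D).
#' @param params An [aln_params()] object.
#' @return Fragment: list with integer `ops` (0=M,1=I,2=D), `lens`, and
#'   `score`.
#' @export
nw_global <- function(query, target, params = aln_params()) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq == 0L && nt == 0L) return(empty_fragment())
  if (nq == 0L)
    return(list(ops = 2L, lens = nt, score = params$gap_extend * nt))
  if (nt == 0L)
    return(list(ops = 1L, lens = nq, score = params$gap_extend * nq))
  al <- banded_align_cpp(query, target, params$match_score,
                         params$mismatch_pen, params$gap_extend,
                         FALSE, FALSE, band_for(params, nq, nt))
  list(ops = al$ops, lens = al$lens, score = al$score)
}

#' Semi-global alignment (free target overhangs)
#'
#' The query must align end-to-end; leading and trailing gaps on the
#' target side are not penalised, which localises the query inside a
#' longer target — the device used to pin down structural-variant
#' breakpoints inside a gap pair. The unaligned target overhangs are
#' reported so the caller can re-emit them (as D or I runs) and keep base
#' conservation.
#'
#' @inheritParams nw_global
#' @return Fragment as in [nw_global()] plus `t_start` (leading overhang
#'   length) and `t_used` (target bases consumed by the CIGAR).
#' @export
semi_global <- function(query, target, params = aln_params()) {
  nq <- nchar(query); nt <- nchar(target)
  if (nq == 0L)
    return(c(empty_fragment(), list(t_start = 0L, t_used = 0L)))
  if (nt == 0L)
    return(list(ops = 1L, lens = nq, score = params$gap_extend * nq,
                t_start = 0L, t_used = 0L))
  al <- banded_align_cpp(query, target, params$match_score,
                         params$mismatch_pen, params$gap_extend,
                         TRUE, TRUE, band_for(params, nq, nt))
  list(ops = al$ops, lens = al$lens, score = al$score,
       t_start = al$t_start, t_used = al$t_used)
}

#' Classify one gap pair
#'
#' A gap pair `(S_R, S_G)` — the unaligned read and reference segments
#' between two consecutive skeleton anchors — is `empty` when both are
#' length 0, a `deletion` candidate when the reference segment is more
#' than `(1+mu)` times the read segment, an `insertion` candidate in the
#' mirrored case, and `match` otherwise.
#'
#' @param len_read,len_ref Segment lengths `L(S_R)`, `L(S_G)` (>= 0).
#' @param mu Threshold (default 2).
#' @return One of `"empty"`, `"match"`, `"deletion"`, `"insertion"`
#'   (vectorised).
#' @export
classify_gap <- function(len_read, len_ref, mu = 2) {
  dplyr::case_when(
    len_read == 0 & len_ref == 0 ~ "empty",
    len_ref > (1 + mu) * len_read ~ "deletion",
    len_read > (1 + mu) * len_ref ~ "insertion",
    TRUE ~ "match"
  )
}

# Collapse a refined skeleton into non-overlapping exact-match diagonal
# blocks. Anchors on one diagonal that overlap merge into a longer block;
# an anchor overlapping the previous block across a different diagonal is
# trimmed from its start by the same amount on both axes (the suffix of an
# exact match is still an exact match) or dropped if nothing remains.
skeleton_blocks <- function(skel) {
  n <- nrow(skel)
  ref_s <- integer(0); ref_e <- integer(0)
  read_s <- integer(0); read_e <- integer(0)
  for (i in seq_len(n)) {
    rs <- skel$ref_pos[i]; qs <- skel$read_pos[i]; len <- skel$length[i]
    m <- length(ref_s)
    if (m > 0L) {
      trim <- max(ref_e[m] - rs, read_e[m] - qs, 0L)
      if (trim >= len) next
      if (trim > 0L && (rs - qs) == (ref_e[m] - read_e[m])) {
        # same diagonal: extend the block
        ref_e[m] <- rs + len; read_e[m] <- qs + len
        next
      }
      rs <- rs + trim; qs <- qs + trim; len <- len - trim
    }
    ref_s <- c(ref_s, rs); ref_e <- c(ref_e, rs + len)
    read_s <- c(read_s, qs); read_e <- c(read_e, qs + len)
  }
  tibble(ref_start = ref_s, ref_end = ref_e,
         read_start = read_s, read_end = read_e)
}

#' Partition read and reference into gap pairs along the skeleton
#'
#' After merging overlapping anchors into exact-match blocks, the region
#' between consecutive blocks on each axis is one inner gap pair; the read
#' prefix before the first block and the suffix after the last are the two
#' boundary pairs, handled by [extend_boundaries()]. A skeleton of n
#' non-overlapping anchors yields n-1 inner pairs.
#'
#' @param skel Refined skeleton tibble (single chromosome).
#' @param read_seq Read sequence (alignment orientation).
#' @param ref_seq Sequence of the skeleton's chromosome.
#' @param mu Classification threshold.
#' @return List with `blocks` (exact-match blocks) and `gaps`, a tibble of
#'   inner gap pairs (`read_start`, `read_end`, `ref_start`, `ref_end`,
#'   `read_seg`, `ref_seg`, `category`).
#' @export
partition_gaps <- function(skel, read_seq, ref_seq, mu = 2) {
  stopifnot(nrow(skel) >= 1L)
  blocks <- skeleton_blocks(skel)
  nb <- nrow(blocks)
  if (nb < 2L) {
    gaps <- tibble(read_start = integer(0), read_end = integer(0),
                   ref_start = integer(0), ref_end = integer(0),
                   read_seg = character(0), ref_seg = character(0),
                   category = character(0))
    return(list(blocks = blocks, gaps = gaps))
  }
  gaps <- tibble(
    read_start = blocks$read_end[-nb], read_end = blocks$read_start[-1L],
    ref_start = blocks$ref_end[-nb], ref_end = blocks$ref_start[-1L])
  gaps$read_seg <- substring(read_seq, gaps$read_start + 1L, gaps$read_end)
  gaps$ref_seg <- substring(ref_seq, gaps$ref_start + 1L, gaps$ref_end)
  gaps$category <- classify_gap(gaps$read_end - gaps$read_start,
                                gaps$ref_end - gaps$ref_start, mu)
  list(blocks = blocks, gaps = gaps)
}

#' Fill one classified gap pair
#'
#' Match gaps get a global end-to-end alignment of read against reference
#' segment. Deletion gaps (reference segment much longer) get a
#' semi-global alignment with the reference segment as target, the free
#' target overhangs re-emitted as D runs — so a deleted reference stretch
#' of any size costs nothing and the breakpoints fall where the flanking
#' bases fit best. Insertion gaps mirror this with the READ segment as
#' target: the free overhangs are unaligned read bases, re-emitted as I
#' runs, and the returned CIGAR is re-expressed in read-as-query
#' orientation (I and D swapped from the internal DP). Empty gaps return
#' an empty fragment. Every returned fragment conserves both segments:
#' query ops sum to `L(S_R)` and reference ops to `L(S_G)`.
#'
#' @param read_seg,ref_seg The gap pair's sequences.
#' @param category From [classify_gap()].
#' @param params An [aln_params()] object.
#' @return Fragment list (`ops`, `lens`, `score`).
#' @export
fill_gap <- function(read_seg, ref_seg, category, params = aln_params()) {
  switch(category,
    empty = empty_fragment(),
    match = nw_global(read_seg, ref_seg, params),
    deletion = {
      al <- semi_global(read_seg, ref_seg, params)
      lead <- al$t_start
      trail <- nchar(ref_seg) - al$t_start - al$t_used
      cg <- cigar_canonical(c(2L, al$ops, 2L), c(lead, al$lens, trail))
      list(ops = cg$ops, lens = cg$lens, score = al$score)
    },
    insertion = {
      al <- semi_global(ref_seg, read_seg, params)
      lead <- al$t_start
      trail <- nchar(read_seg) - al$t_start - al$t_used
      swapped <- ifelse(al$ops == 1L, 2L, ifelse(al$ops == 2L, 1L, 0L))
      cg <- cigar_canonical(c(1L, swapped, 1L), c(lead, al$lens, trail))
      list(ops = cg$ops, lens = cg$lens, score = al$score)
    },
    stop("unknown gap category: ", category, call. = FALSE)
  )
}

#' Extend the skeleton boundaries so the whole read aligns
#'
#' The read suffix after the last exact-match block is aligned against a
#' reference window of twice its length (clipped at the chromosome end)
#' with a modified global alignment: global on the read, but the gap at
#' the query end — the unreached tail of the reference window — is not
#' penalised and simply ends the alignment. The prefix before the first
#' block is handled mirror-wise (free leading reference overhang). The
#' boundary regions are assumed free of structural variants. Both
#' fragments always consume the entire read prefix/suffix: if the clipped
#' window is shorter than the query, the surplus read bases align as I.
#' This is what guarantees zero soft-clipping in the final record.
#'
#' @param blocks Block tibble from [partition_gaps()].
#' @param read_seq Read sequence (alignment orientation).
#' @param ref_seq Chromosome sequence.
#' @param params An [aln_params()] object.
#' @return List `left`/`right` fragments plus `ref_start`/`ref_end`, the
#'   final outer reference coordinates of the alignment.
#' @export
extend_boundaries <- function(blocks, read_seq, ref_seq,
                              params = aln_params()) {
  nb <- nrow(blocks)
  read_len <- nchar(read_seq); ref_len <- nchar(ref_seq)
  # right: suffix after the last block
  suf_len <- read_len - blocks$read_end[nb]
  if (suf_len == 0L) {
    right <- empty_fragment(); ref_end <- blocks$ref_end[nb]
  } else {
    query <- substring(read_seq, blocks$read_end[nb] + 1L, read_len)
    t_end <- min(ref_len, blocks$ref_end[nb] + 2L * suf_len)
    target <- substring(ref_seq, blocks$ref_end[nb] + 1L, t_end)
    al <- banded_align_cpp(query, target, params$match_score,
                           params$mismatch_pen, params$gap_extend,
                           FALSE, TRUE,
                           band_for(params, suf_len, nchar(target)))
    right <- list(ops = al$ops, lens = al$lens, score = al$score)
    ref_end <- blocks$ref_end[nb] + al$t_used
  }
  # left: prefix before the first block, via reversal
  pre_len <- blocks$read_start[1L]
  if (pre_len == 0L) {
    left <- empty_fragment(); ref_start <- blocks$ref_start[1L]
  } else {
    query <- rev_string(substring(read_seq, 1L, pre_len))
    t_start <- max(0L, blocks$ref_start[1L] - 2L * pre_len)
    target <- rev_string(substring(ref_seq, t_start + 1L,
                                   blocks$ref_start[1L]))
    al <- banded_align_cpp(query, target, params$match_score,
                           params$mismatch_pen, params$gap_extend,
                           FALSE, TRUE,
                           band_for(params, pre_len, nchar(target)))
    left <- list(ops = rev(al$ops), lens = rev(al$lens), score = al$score)
    ref_start <- blocks$ref_start[1L] - al$t_used
  }
  list(left = left, right = right, ref_start = ref_start, ref_end = ref_end)
}

rev_string <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Assemble the end-to-end alignment record for one read
#'
#' Concatenates the left boundary fragment, the alternating exact-match
#' block M runs and inner gap fills, and the right boundary fragment;
#' merges adjacent same-type CIGAR runs; and recomputes base counts and
#' the alignment score (match +1, mismatch -1, each indel run -(length+1):
#' one gap open plus one extend per base) against the sequences. The
#' assembled CIGAR always consumes the read end-to-end — a conservation
#' violation is a bug and raises an error.
#'
#' @param skel Refined skeleton (single chromosome).
#' @param read_seq Read sequence in alignment orientation.
#' @param ref_seq Chromosome sequence.
#' @param params An [aln_params()] object.
#' @return One-row tibble: `chrom` (integer index), `ref_start`,
#'   `ref_end`, `cigar`, `score`, `n_match`, `n_mismatch`, `n_ins`,
#'   `n_del`.
#' @export
assemble_alignment <- function(skel, read_seq, ref_seq,
                               params = aln_params()) {
  part <- partition_gaps(skel, read_seq, ref_seq, params$mu)
  blocks <- part$blocks; gaps <- part$gaps
  bounds <- extend_boundaries(blocks, read_seq, ref_seq, params)
  nb <- nrow(blocks)
  ops <- list(bounds$left$ops)
  lens <- list(bounds$left$lens)
  for (i in seq_len(nb)) {
    ops[[length(ops) + 1L]] <- 0L
    lens[[length(lens) + 1L]] <- blocks$ref_end[i] - blocks$ref_start[i]
    if (i < nb) {
      fr <- fill_gap(gaps$read_seg[i], gaps$ref_seg[i], gaps$category[i],
                     params)
      ops[[length(ops) + 1L]] <- fr$ops
      lens[[length(lens) + 1L]] <- fr$lens
    }
  }
  ops[[length(ops) + 1L]] <- bounds$right$ops
  lens[[length(lens) + 1L]] <- bounds$right$lens
  cg <- cigar_canonical(unlist(ops), unlist(lens))
  if (cigar_query_len(cg$ops, cg$lens) != nchar(read_seq) ||
      cigar_ref_len(cg$ops, cg$lens) != bounds$ref_end - bounds$ref_start)
    stop("alignment assembly violated base conservation (internal error)",
         call. = FALSE)
  st <- cigar_stats_cpp(read_seq, ref_seq, cg$ops, cg$lens, bounds$ref_start)
  gap_runs <- cg$ops %in% c(1L, 2L)
  score <- st$n_match * params$match_score +
    st$n_mismatch * params$mismatch_pen +
    sum(gap_runs) * params$gap_open +
    (st$n_ins + st$n_del) * params$gap_extend
  tibble(chrom = skel$chrom[1L], ref_start = bounds$ref_start,
         ref_end = bounds$ref_end, cigar = cigar_string(cg), score = score,
         n_match = st$n_match, n_mismatch = st$n_mismatch,
         n_ins = st$n_ins, n_del = st$n_del)
}
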