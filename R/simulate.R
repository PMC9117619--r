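#' Error profile of the read simulator
#'
#' Per-reference-base channel rates of the indel-dominated error model
#' typical of single-molecule long reads: 8% deletions, 7% insertions, 1%
#' substitutions (16% total) by default. `total` rescales all three
#' channels proportionally, e.g. `error_profile(total = 0.20)` for a
#' 20%-error dataset.
#'
#' @param del_rate,ins_rate,sub_rate Per-base channel probabilities.
#' @param total Optional total error rate; rescales the three rates to
#'   this sum while preserving their ratios.
#' @return List of class `error_profile`.
#' @export
error_profile <- function(del_rate = 0.08, ins_rate = 0.07,
                          sub_rate = 0.01, total = NULL) {
  if (!is.null(total)) {
    s <- del_rate + ins_rate + sub_rate
    del_rate <- del_rate * total / s
    ins_rate <- ins_rate * total / s
    sub_rate <- sub_rate * total / s
  }
  stopifnot(del_rate >= 0, ins_rate >= 0, sub_rate >= 0,
            del_rate + ins_rate + sub_rate < 1)
  structure(list(del_rate = del_rate, ins_rate = ins_rate,
                 sub_rate = sub_rate), class = "error_profile")
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Generate a random reference sequence
#'
#' I.i.d. bases at the requested GC content; deterministic for a fixed
#' seed.
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param gc GC fraction (default 0.5).
#' @param id Sequence name.
#' @return One-row tibble (`id`, `seq`).
#' @export
generate_genome <- function(length, seed = NULL, gc = 0.5, id = "chr1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_opt_seed(seed, paste(
    sample(names(p), length, replace = TRUE, prob = p), collapse = ""))
  tibble(id = id, seq = seq)
}

#' Declare structural variants to inject
#'
#' @param sv_type Character vector over `insertion`, `deletion`,
#'   `inversion`.
#' @param size Sizes in bases (>= 1).
#' @param pos Optional 0-based positions on the original genome
#'   (breakpoint start); `NA` for random placement.
#' @return Tibble of SV specifications.
#' @export
sv_spec <- function(sv_type, size, pos = NA_integer_) {
  stopifnot(all(sv_type %in% c("insertion", "deletion", "inversion")),
            all(size >= 1))
  tibble(sv_type = sv_type, size = as.integer(size),
         pos = as.integer(pos))
}

#' Inject structural variants into a genome
#'
#' Produces the mutated genome plus, per SV, the ground-truth breakpoint
#' tuple in ORIGINAL reference coordinates: a deletion records its deleted
#' interval `[bp_start, bp_end)`, an insertion its zero-length locus
#' `(p, p)`, an inversion its inverted interval. Insertions introduce
#' novel random sequence; inversions reverse-complement in place.
#' Placements must not overlap (randomly placed SVs are drawn until
#' disjoint, with a margin of one base). A coordinate map from mutated to
#' original positions is returned so that reads simulated from the
#' mutated genome can be evaluated against the original reference.
#'
#' @param genome One-row tibble (`id`, `seq`).
#' @param specs Tibble from [sv_spec()].
#' @param seed Integer seed or `NULL`.
#' @return List: `genome` (mutated, one-row tibble), `svs` (SV truth
#'   tibble: `sv_type`, `chrom`, `bp_start`, `bp_end`, `size`), `coord_map`
#'   (segment table for [mut_to_orig()]).
#' @export
inject_svs <- function(genome, specs, seed = NULL) {
  stopifnot(nrow(genome) == 1L)
  g <- genome$seq[[1]]
  glen <- nchar(g)
  if (sum(specs$size[specs$sv_type == "deletion"]) >= glen)
    stop("total deletion size exceeds genome length", call. = FALSE)
  with_opt_seed(seed, {
    span <- ifelse(specs$sv_type == "insertion", 0L, specs$size)
    pos <- specs$pos
    for (i in order(is.na(pos))) { # keep requested positions first
      if (is.na(pos[i])) {
        ok <- FALSE
        for (try in 1:1000) {
          cand <- sample.int(glen - max(span[i], 1L) - 1L, 1L)
          sep <- is.na(pos[-i]) | cand + span[i] + 1L < pos[-i] |
            cand > (pos[-i] + span[-i] + 1L)
          if (all(sep)) { pos[i] <- cand; ok <- TRUE; break }
        }
        if (!ok) stop("could not place non-overlapping SVs", call. = FALSE)
      }
    }
    o <- order(pos)
    specs <- specs[o, ]; pos <- pos[o]; span <- span[o]
    if (any(pos[-1L] < (pos[-length(pos)] + span[-length(span)])))
      stop("requested SV placements overlap", call. = FALSE)
    if (any(pos + span > glen))
      stop("SV extends past the end of the genome", call. = FALSE)

    pieces <- character(0)
    # coord map rows: each mutated-genome segment and its original anchor
    ms <- integer(0); os <- integer(0); ln <- integer(0); ty <- character(0)
    cur_orig <- 0L; cur_mut <- 0L
    add_seg <- function(len, orig, type) {
      ms <<- c(ms, cur_mut); os <<- c(os, orig); ln <<- c(ln, len)
      ty <<- c(ty, type); cur_mut <<- cur_mut + len
    }
    for (i in seq_len(nrow(specs))) {
      lead <- pos[i] - cur_orig
      if (lead > 0L) {
        pieces <- c(pieces, substring(g, cur_orig + 1L, pos[i]))
        add_seg(lead, cur_orig, "copy")
      }
      if (specs$sv_type[i] == "deletion") {
        cur_orig <- pos[i] + specs$size[i]
      } else if (specs$sv_type[i] == "insertion") {
        ins <- paste(sample(c("A", "C", "G", "T"), specs$size[i],
                            replace = TRUE), collapse = "")
        pieces <- c(pieces, ins)
        add_seg(specs$size[i], pos[i], "insertion")
        cur_orig <- pos[i]
      } else { # inversion
        seg <- substring(g, pos[i] + 1L, pos[i] + specs$size[i])
        pieces <- c(pieces, reverse_complement(seg))
        add_seg(specs$size[i], pos[i], "inversion")
        cur_orig <- pos[i] + specs$size[i]
      }
    }
    if (cur_orig < glen) {
      pieces <- c(pieces, substring(g, cur_orig + 1L, glen))
      add_seg(glen - cur_orig, cur_orig, "copy")
    }
    svs <- tibble(sv_type = specs$sv_type, chrom = genome$id[[1]],
                  bp_start = pos,
                  bp_end = ifelse(specs$sv_type == "insertion", pos,
                                  pos + specs$size),
                  size = specs$size)
    list(genome = tibble(id = genome$id[[1]],
                         seq = paste(pieces, collapse = "")),
         svs = svs,
         coord_map = tibble(mut_start = ms, orig_start = os, len = ln,
                            type = ty))
  })
}

#' Map mutated-genome positions back to original coordinates
#'
#' Positions inside an inserted segment map to the insertion locus;
#' positions in copied or inverted segments map linearly (an inversion
#' preserves its interval). Used to express simulated read intervals in
#' the coordinates of the original (pre-SV) reference they are mapped
#' against.
#'
#' @param pos Integer vector of 0-based mutated-genome positions.
#' @param coord_map From [inject_svs()].
#' @return Integer vector of original-genome positions.
#' @export
mut_to_orig <- function(pos, coord_map) {
  seg <- findInterval(pos, coord_map$mut_start)
  if (any(seg < 1L | pos < 0L))
    stop("position outside the mutated genome", call. = FALSE)
  off <- pos - coord_map$mut_start[seg]
  over <- off > coord_map$len[seg] # only possible past the last segment
  if (any(over)) off[over] <- coord_map$len[seg[over]]
  ifelse(coord_map$type[seg] == "insertion",
         coord_map$orig_start[seg],
         coord_map$orig_start[seg] + off)
}

#' Simulate long noisy reads with per-read truth
#'
#' Each read draws a uniform start, a uniform target length within
#' `len_range`, and a uniform strand, then passes the reference window
#' through the error channel of [error_profile()]: for every reference
#' base, independently insert a random base before it (prob `ins_rate`),
#' delete it (prob `del_rate`), else substitute it (prob `sub_rate`) —
#' so the realized marginal rate of each channel equals its nominal rate.
#' The truth CIGAR records the exact read-to-reference correspondence in
#' reference-forward orientation (for `-` reads it describes the
#' reverse complement of the emitted read, the same orientation a SAM
#' record uses).
#'
#' @param genome One-row tibble (`id`, `seq`).
#' @param n_reads Number of reads.
#' @param len_range Min/max read length in bases.
#' @param profile An [error_profile()].
#' @param seed Integer seed or `NULL`.
#' @param id_prefix Read-name prefix.
#' @return List: `reads` (tibble `id`, `seq`) and `truth` (tibble
#'   `read_id`, `chrom`, `strand`, `ref_start`, `ref_end`, `truth_cigar`,
#'   `read_len`).
#' @export
simulate_reads <- function(genome, n_reads, len_range = c(1000L, 10000L),
                           profile = error_profile(), seed = NULL,
                           id_prefix = "read") {
  stopifnot(nrow(genome) == 1L, len_range[1] >= 1,
            len_range[2] <= nchar(genome$seq[[1]]))
  g <- genome$seq[[1]]
  glen <- nchar(g)
  with_opt_seed(seed, {
    ids <- sprintf("%s_%0*d", id_prefix, nchar(as.character(n_reads)),
                   seq_len(n_reads))
    seqs <- character(n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      L <- sample(len_range[1]:len_range[2], 1L)
      # leave room for the ~1% expected read-vs-reference contraction
      max_start <- max(0L, glen - ceiling(1.15 * L))
      s <- sample.int(max_start + 1L, 1L) - 1L
      sim <- simulate_read_cpp(g, s, L, profile$del_rate,
                               profile$ins_rate, profile$sub_rate)
      strand <- if (runif(1) < 0.5) "+" else "-"
      seqs[i] <- if (strand == "+") sim$seq else reverse_complement(sim$seq)
      truth[[i]] <- tibble(
        read_id = ids[i], chrom = genome$id[[1]], strand = strand,
        ref_start = sim$ref_start, ref_end = sim$ref_end,
        truth_cigar = cigar_string(list(ops = sim$ops, lens = sim$lens)),
        read_len = nchar(sim$seq))
    }
    list(reads = tibble(id = ids, seq = seqs),
         truth = dplyr::bind_rows(truth))
  })
}

#' Express simulated-read truth intervals in original coordinates
#'
#' For reads simulated from an SV-mutated genome, converts each truth
#' interval to the original (pre-SV) reference coordinates via the
#' injection's coordinate map, appending `orig_start`/`orig_end` columns.
#' A read whose `[orig_start, orig_end)` strictly contains an SV's
#' breakpoint interval is, by construction, an SV-spanning read.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param coord_map From [inject_svs()].
#' @return `truth` with `orig_start` and `orig_end` appended.
#' @export
truth_to_original <- function(truth, coord_map) {
  truth$orig_start <- mut_to_orig(truth$ref_start, coord_map)
  truth$orig_end <- mut_to_orig(truth$ref_end, coord_map)
  truth
}
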