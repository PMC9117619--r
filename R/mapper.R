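#' Mapper configuration
#'
#' Bundles every tunable of the pipeline. Defaults: `k = 15` (anchor
#' k-mer length), `lam = 1.2` (neighborhood distance multiplier, so
#' `d = 1.2 * read length`), `alpha = 1` (constant chaining reward),
#' `mu = 2` (gap category threshold), refinement window equal to the read
#' length (`window = NULL`), reads shorter than `min_read_len = 1000` bp
#' filtered out, and k-mers with more than `freq_cap = 500` reference
#' occurrences masked. Mapping uses no randomness, so results are
#' reproducible by construction and identical for any `threads` value.
#'
#' @param k K-mer length.
#' @param lam Distance-scale multiplier for [compute_d()].
#' @param alpha Chaining edge reward.
#' @param mu Gap classification threshold.
#' @param window Refinement window in reference bases, or `NULL` for the
#'   read length.
#' @param min_read_len Minimum read length retained.
#' @param freq_cap Index frequency mask.
#' @param min_anchors Minimum refined-skeleton size for a read to count
#'   as mapped (default 2: one isolated k-mer hit is not evidence).
#' @param threads Worker processes for [map_reads()].
#' @return List of class `map_config`.
#' @export
map_config <- function(k = 15L, lam = 1.2, alpha = 1, mu = 2,
                       window = NULL, min_read_len = 1000L,
                       freq_cap = 500L, min_anchors = 2L, threads = 1L) {
  stopifnot(min_read_len >= k)
  structure(list(k = as.integer(k), lam = lam, alpha = alpha, mu = mu,
                 window = window, min_read_len = as.integer(min_read_len),
                 freq_cap = as.integer(freq_cap),
                 min_anchors = as.integer(min_anchors),
                 threads = as.integer(threads)),
            class = "map_config")
}

unmapped_record <- function(read_id, seq) {
  tibble(read_id = read_id, mapped = FALSE, chrom = NA_character_,
         strand = NA_character_, ref_start = NA_integer_,
         ref_end = NA_integer_, cigar = NA_character_, score = NA_real_,
         n_match = NA_real_, n_mismatch = NA_real_, n_ins = NA_real_,
         n_del = NA_real_, read_len = nchar(seq), seq = seq)
}

map_one_strand <- function(seq, index, genome, cfg, params) {
  anchors <- extract_anchors(index, seq)
  if (nrow(anchors) == 0L) return(NULL)
  d <- compute_d(nchar(seq), cfg$lam)
  dp <- chain_scores(anchors, d, cfg$alpha)
  skel <- backtrack_skeleton(dp)
  wl <- if (is.null(cfg$window)) nchar(seq) else cfg$window
  skel <- refine_skeleton(skel, wl)
  if (nrow(skel) < cfg$min_anchors) return(NULL)
  ref_seq <- genome$seq[skel$chrom[1L]]
  assemble_alignment(skel, seq, ref_seq, params)
}

#' Map one read end-to-end
#'
#' Runs the full pipeline — anchor extraction, neighborhood-graph
#' chaining, window refinement, gap classification and filling, boundary
#' extension — for the read and for its reverse complement, and keeps the
#' strand whose assembled alignment scores higher (ties go to the forward
#' strand). A read is unmapped when neither strand yields a refined
#' skeleton of at least `cfg$min_anchors` anchors.
#'
#' @param read One-row tibble (`id`, `seq`).
#' @param index A `kmer_index` built with `cfg$k`/`cfg$freq_cap`.
#' @param genome Reference tibble (`id`, `seq`) the index was built from.
#' @param cfg A [map_config()].
#' @return One-row alignment tibble; `seq` holds the read as aligned
#'   (reverse-complemented for `-` records), matching SAM convention.
#' @export
map_read <- function(read, index, genome, cfg = map_config()) {
  params <- aln_params(mu = cfg$mu)
  fwd <- map_one_strand(read$seq[[1]], index, genome, cfg, params)
  rc <- reverse_complement(read$seq[[1]])
  rev <- map_one_strand(rc, index, genome, cfg, params)
  pick <- if (is.null(fwd) && is.null(rev)) NULL
          else if (is.null(rev)) list(fwd, "+", read$seq[[1]])
          else if (is.null(fwd)) list(rev, "-", rc)
          else if (rev$score > fwd$score) list(rev, "-", rc)
          else list(fwd, "+", read$seq[[1]])
  # a non-positive total score is worse than aligning nothing at all:
  # report chance-seeded junk alignments as unmapped
  if (!is.null(pick) && pick[[1]]$score <= 0) pick <- NULL
  if (is.null(pick)) return(unmapped_record(read$id[[1]], read$seq[[1]]))
  rec <- pick[[1]]
  tibble(read_id = read$id[[1]], mapped = TRUE,
         chrom = genome$id[rec$chrom], strand = pick[[2]],
         ref_start = rec$ref_start, ref_end = rec$ref_end,
         cigar = rec$cigar, score = rec$score, n_match = rec$n_match,
         n_mismatch = rec$n_mismatch, n_ins = rec$n_ins,
         n_del = rec$n_del, read_len = nchar(read$seq[[1]]),
         seq = pick[[3]])
}

#' Map a set of reads
#'
#' Reads shorter than `cfg$min_read_len` are filtered (reported with
#' `filtered = TRUE`, neither mapped nor unmapped-by-failure). Per-read
#' work is independent; with `cfg$threads > 1` reads are mapped in
#' forked workers and results collected in input order, so the output is
#' identical for any thread count.
#'
#' @param reads Tibble (`id`, `seq`), e.g. from [read_seqs()].
#' @param index A `kmer_index`.
#' @param genome Reference tibble the index was built from.
#' @param cfg A [map_config()].
#' @return Tibble with one row per input read, in input order, with a
#'   `filtered` column; attribute `summary` holds mapped/unmapped/filtered
#'   counts.
#' @export
map_reads <- function(reads, index, genome, cfg = map_config()) {
  keep <- nchar(reads$seq) >= cfg$min_read_len
  run_one <- function(i) map_read(reads[i, ], index, genome, cfg)
  idx <- which(keep)
  recs <- if (cfg$threads > 1L)
    parallel::mclapply(idx, run_one, mc.cores = cfg$threads,
                       mc.preschedule = TRUE)
  else lapply(idx, run_one)
  out <- vector("list", nrow(reads))
  out[idx] <- recs
  out[!keep] <- lapply(which(!keep), function(i)
    unmapped_record(reads$id[i], reads$seq[i]))
  res <- dplyr::bind_rows(out)
  res$filtered <- !keep
  attr(res, "summary") <- c(n_reads = nrow(reads),
                            n_filtered = sum(!keep),
                            n_mapped = sum(res$mapped & keep),
                            n_unmapped = sum(!res$mapped & keep))
  res
}

#' Map a read file against a reference file and write SAM
#'
#' Thin orchestration over [read_seqs()], [build_index()], [map_reads()]
#' and [write_sam()]; this is what the `skelmap map` command calls.
#'
#' @param reads_path FASTA/FASTQ of reads.
#' @param ref Reference tibble, `kmer_index`, or path to a reference
#'   FASTA.
#' @param out_path Output SAM path.
#' @param cfg A [map_config()].
#' @param genome Reference tibble; required when `ref` is a prebuilt
#'   index.
#' @return The alignment tibble, invisibly.
#' @export
map_file <- function(reads_path, ref, out_path, cfg = map_config(),
                     genome = NULL) {
  if (inherits(ref, "kmer_index")) {
    index <- ref
    if (is.null(genome))
      stop("genome tibble required when passing a prebuilt index",
           call. = FALSE)
  } else {
    genome <- if (is.data.frame(ref)) ref else read_fasta(ref)
    index <- build_index(genome, k = cfg$k, freq_cap = cfg$freq_cap)
  }
  reads <- read_seqs(reads_path)
  alns <- map_reads(reads, index, genome, cfg)
  write_sam(alns, genome, out_path)
  s <- attr(alns, "summary")
  message(sprintf("mapped %d / unmapped %d / filtered %d of %d reads",
                  s["n_mapped"], s["n_unmapped"], s["n_filtered"],
                  s["n_reads"]))
  invisible(alns)
}
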