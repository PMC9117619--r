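#' Evaluation parameters
#'
#' `cmr_frac`: a read is correctly mapped (CMR) when its alignment sits on
#' the right chromosome and strand and overlaps the truth interval by at
#' least `cmr_frac * read length` bases (default 0.9). `cmb_tol`: a read
#' base is correctly mapped (CMB) when its aligned reference position is
#' within `cmb_tol` bases of its truth position (default 5).
#' `consec_thresholds`: covered-fraction cutoffs for consecutiveness.
#' `agree_frac`: overlap fraction for the pairwise agreement predicate.
#'
#' @param cmr_frac,cmb_tol,consec_thresholds,agree_frac See above.
#' @return List of class `eval_params`.
#' @export
eval_params <- function(cmr_frac = 0.9, cmb_tol = 5L,
                        consec_thresholds = c(0.80, 0.85, 0.90, 0.95),
                        agree_frac = 0.9) {
  stopifnot(cmr_frac > 0, cmr_frac <= 1, cmb_tol >= 0,
            all(consec_thresholds > 0 & consec_thresholds <= 1))
  structure(list(cmr_frac = cmr_frac, cmb_tol = as.integer(cmb_tol),
                 consec_thresholds = consec_thresholds,
                 agree_frac = agree_frac),
            class = "eval_params")
}

interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Correctly-mapped-read predicate
#'
#' TRUE iff the alignment is on the truth chromosome and strand and the
#' reference-interval overlap with the truth interval is at least
#' `frac * read length` (inclusive). Vectorised over rows.
#'
#' @param truth,aln Tibbles (or one-row slices) with `chrom`, `strand`,
#'   `ref_start`, `ref_end`; `truth` additionally needs `read_len` (or
#'   pass `read_len`).
#' @param frac Overlap fraction (default 0.9).
#' @param read_len Read lengths; defaults to `truth$read_len`.
#' @return Logical vector.
#' @export
is_cmr <- function(truth, aln, frac = 0.9, read_len = truth$read_len) {
  ov <- interval_overlap(truth$ref_start, truth$ref_end,
                         aln$ref_start, aln$ref_end)
  !is.na(aln$ref_start) & truth$chrom == aln$chrom &
    truth$strand == aln$strand & ov >= frac * read_len
}

#' Count correctly mapped bases for one read
#'
#' Both CIGARs are walked to the per-read-base reference position (in
#' alignment orientation); a base counts when both alignments place it
#' and the two positions differ by at most `tol`. Bases inserted (I) in
#' either alignment carry no position and never count; reads mapped to
#' the wrong chromosome or strand contribute zero.
#'
#' @param truth One-row truth slice (`strand`, `chrom`, `ref_start`,
#'   `truth_cigar`).
#' @param aln One-row alignment slice (`strand`, `chrom`, `ref_start`,
#'   `cigar`).
#' @param tol Base tolerance (default 5).
#' @return Number of correctly mapped bases.
#' @export
count_cmb <- function(truth, aln, tol = 5L) {
  if (is.na(aln$cigar) || is.na(aln$chrom) ||
      truth$chrom != aln$chrom || truth$strand != aln$strand)
    return(0L)
  pt <- cigar_ref_positions(truth$truth_cigar, truth$ref_start)
  pa <- cigar_ref_positions(aln$cigar, aln$ref_start)
  if (length(pt) != length(pa))
    stop("truth and alignment disagree on read length for read pair",
         call. = FALSE)
  sum(!is.na(pt) & !is.na(pa) & abs(pt - pa) <= tol)
}

#' Aligned coverage of one record
#'
#' Fraction of the read's bases included in the alignment: query-consuming
#' non-clipped CIGAR bases (M and I) over the read length. End-to-end
#' records score exactly 1.
#'
#' @param cigar CIGAR string (vectorised).
#' @param read_len Read length(s).
#' @return Numeric fraction(s) in `[0, 1]`; `NA` for unmapped.
#' @export
aligned_coverage <- function(cigar, read_len) {
  mapply(function(cg, n) {
    if (is.na(cg)) return(NA_real_)
    p <- cigar_parse(cg)
    sum(p$lens[p$ops %in% c(0L, 1L)]) / n
  }, cigar, read_len, USE.NAMES = FALSE)
}

#' Consecutiveness at coverage thresholds
#'
#' Percentage of mapped reads whose single reported alignment covers at
#' least each threshold fraction of the read; monotone non-increasing in
#' the threshold.
#'
#' @param coverage Aligned-coverage fractions of the mapped reads.
#' @param thresholds Coverage cutoffs (default 80/85/90/95%).
#' @return Named numeric vector of percentages.
#' @export
consecutiveness <- function(coverage, thresholds = c(0.80, 0.85, 0.90, 0.95)) {
  coverage <- coverage[!is.na(coverage)]
  out <- vapply(thresholds,
                function(ci) 100 * mean(coverage >= ci), numeric(1))
  setNames(out, sprintf("c%g", 100 * thresholds))
}

#' Breakpoint-spanning predicate
#'
#' An alignment recovers a breakpoint iff its mapped reference interval
#' strictly contains the breakpoint interval: `ref_start < bp_start` and
#' `ref_end > bp_end`. Vectorised over alignments.
#'
#' @param aln Alignment tibble (`chrom`, `ref_start`, `ref_end`).
#' @param bp One breakpoint (`chrom`, `bp_start`, `bp_end`).
#' @return Logical vector.
#' @export
sv_spanning <- function(aln, bp) {
  !is.na(aln$ref_start) & aln$chrom == bp$chrom &
    aln$ref_start < bp$bp_start & aln$ref_end > bp$bp_end
}

#' Pairwise agreement of two alignments of the same read
#'
#' `a1` agrees with (covers) `a2` iff the overlap of their outer mapped
#' reference intervals is at least `frac` of `a2`'s interval — an
#' asymmetric predicate: a long alignment can cover a short one and not
#' conversely.
#'
#' @param a1,a2 Alignment slices (`chrom`, `ref_start`, `ref_end`).
#' @param frac Coverage fraction (default 0.9).
#' @return Logical vector.
#' @export
agreement <- function(a1, a2, frac = 0.9) {
  ov <- interval_overlap(a1$ref_start, a1$ref_end, a2$ref_start, a2$ref_end)
  !is.na(a1$ref_start) & !is.na(a2$ref_start) & a1$chrom == a2$chrom &
    ov >= frac * (a2$ref_end - a2$ref_start)
}

#' Recompute the alignment score of a record from sequences
#'
#' Walks the CIGAR against the read (alignment orientation) and the
#' reference: match +1, mismatch -1, each maximal I or D run -(length+1)
#' (one gap open plus one extend per base), clipped bases -1 each with no
#' open.
#'
#' @param aln One-row alignment slice (`cigar`, `ref_start`, `seq`).
#' @param ref_seq Sequence of the record's chromosome.
#' @return Numeric score.
#' @export
alignment_score <- function(aln, ref_seq) {
  cg <- cigar_parse(aln$cigar)
  clip <- cg$ops == 3L
  core <- list(ops = cg$ops[!clip], lens = cg$lens[!clip])
  seq_core <- aln$seq
  if (any(clip)) { # strip clipped bases from the query before walking
    qpos <- rep.int(cg$ops, cg$lens)
    keep <- qpos[qpos != 2L] != 3L
    seq_core <- paste(strsplit(aln$seq, "")[[1]][keep], collapse = "")
  }
  st <- cigar_stats_cpp(seq_core, ref_seq, core$ops, core$lens,
                        aln$ref_start)
  gap_runs <- sum(core$ops %in% c(1L, 2L))
  st$n_match - st$n_mismatch - (st$n_ins + st$n_del) - gap_runs -
    sum(cg$lens[clip])
}

#' Evaluate a mapping run against simulated truth
#'
#' Joins alignments to per-read truth and computes the full metric panel:
#' CMR and CMB counts, aggregate aligned coverage, base-level sensitivity
#' (correct bases over all bases, mapped or not) and precision (correct
#' bases over mapped bases), and consecutiveness at the four thresholds.
#'
#' @param alns Alignment tibble from [map_reads()] or [read_sam()] (needs
#'   `read_len`; [read_sam()] output gets it from the truth join).
#' @param truth Truth tibble from [simulate_reads()] / [read_truth()].
#' @param params An [eval_params()].
#' @return Object of class `skelmap_eval`: a list with `per_read` (tidy
#'   per-read tibble) and `metrics` (one-row summary tibble).
#' @export
evaluate_mapping <- function(alns, truth, params = eval_params()) {
  stopifnot(all(truth$read_id %in% alns$read_id) ||
              all(alns$read_id %in% truth$read_id))
  tb <- dplyr::inner_join(
    truth,
    dplyr::select(alns, "read_id", aln_chrom = "chrom",
                  aln_strand = "strand", aln_start = "ref_start",
                  aln_end = "ref_end", aln_cigar = "cigar", "mapped"),
    by = "read_id")
  tb$coverage <- aligned_coverage(tb$aln_cigar, tb$read_len)
  tb$cmr <- is_cmr(
    tb,
    tibble(chrom = tb$aln_chrom, strand = tb$aln_strand,
           ref_start = tb$aln_start, ref_end = tb$aln_end),
    frac = params$cmr_frac)
  tb$cmb <- vapply(seq_len(nrow(tb)), function(i) {
    count_cmb(
      tb[i, c("chrom", "strand", "ref_start", "truth_cigar")],
      tibble(chrom = tb$aln_chrom[i], strand = tb$aln_strand[i],
             ref_start = tb$aln_start[i], cigar = tb$aln_cigar[i]),
      tol = params$cmb_tol)
  }, numeric(1))
  mapped_bases <- sum(tb$coverage * tb$read_len, na.rm = TRUE)
  total_bases <- sum(tb$read_len)
  metrics <- tibble(
    n_reads = nrow(tb),
    n_mapped = sum(tb$mapped),
    n_cmr = sum(tb$cmr),
    n_cmb = sum(tb$cmb),
    aligned_coverage_pct =
      100 * mapped_bases / sum(tb$read_len[tb$mapped]),
    sensitivity_pct = if (total_bases > 0) 100 * sum(tb$cmb) / total_bases
                      else NaN,
    precision_pct = if (mapped_bases > 0) 100 * sum(tb$cmb) / mapped_bases
                    else NaN)
  cons <- consecutiveness(tb$coverage[tb$mapped], params$consec_thresholds)
  for (nm in names(cons))
    metrics[[paste0("consec_", nm, "_pct")]] <- unname(cons[[nm]])
  structure(list(per_read = tb, metrics = metrics, params = params),
            class = "skelmap_eval")
}

#' Summarise breakpoint recovery over SV-spanning reads
#'
#' For each truth-spanning read (truth interval in original coordinates
#' strictly containing the breakpoint interval), checks whether its
#' reported alignment also spans the breakpoint.
#'
#' @param alns Alignment tibble.
#' @param truth Truth tibble carrying `orig_start`/`orig_end` from
#'   [truth_to_original()].
#' @param svs SV truth tibble from [inject_svs()].
#' @return Tibble with one row per (spanning read, SV) pair and a logical
#'   `recovered`.
#' @export
sv_recovery <- function(alns, truth, svs) {
  out <- list()
  for (i in seq_len(nrow(svs))) {
    bp <- svs[i, ]
    spanning <- truth[truth$chrom == bp$chrom &
                        truth$orig_start < bp$bp_start &
                        truth$orig_end > bp$bp_end, ]
    if (!nrow(spanning)) next
    al <- alns[match(spanning$read_id, alns$read_id), ]
    out[[length(out) + 1L]] <- tibble(
      read_id = spanning$read_id, sv_type = bp$sv_type,
      bp_start = bp$bp_start, bp_end = bp$bp_end,
      recovered = sv_spanning(al, bp))
  }
  dplyr::bind_rows(out)
}

#' @export
print.skelmap_eval <- function(x, ...) {
  cat("<skelmap_eval>", x$metrics$n_reads, "reads,",
      x$metrics$n_mapped, "mapped\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}
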