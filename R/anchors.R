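#' Extract exact k-mer match anchors for one read
#'
#' Every k-mer of the read is looked up in the reference index; each
#' (read occurrence, reference occurrence) pair becomes one anchor
#' `(chrom, ref_pos, read_pos, length = k)`. Anchors are the vertices of
#' the distance-constrained neighborhood graph the chaining stage scores.
#'
#' @param index A `kmer_index` from [build_index()].
#' @param read One-row tibble (`id`, `seq`) or a plain sequence string.
#' @return Tibble of anchors sorted by (chrom, ref_pos, read_pos), with
#'   duplicates removed; `chrom` is an integer index into
#'   `index$chrom_names`. Zero rows when the read shares no k-mer with
#'   the indexed reference.
#' @export
extract_anchors <- function(index, read) {
  stopifnot(inherits(index, "kmer_index"))
  seq <- if (is.data.frame(read)) read$seq[[1]] else read
  if (nchar(seq) < index$k)
    stop("read shorter than k = ", index$k, call. = FALSE)
  codes <- encode_kmers_cpp(seq, index$k)
  hit <- match_codes(index, codes)
  ih <- which(!is.na(hit))
  if (!length(ih))
    return(tibble(chrom = integer(0), ref_pos = integer(0),
                  read_pos = integer(0), length = integer(0)))
  runs <- hit[ih]
  n_occ <- index$ptr[runs + 1L] - index$ptr[runs]
  occ_idx <- sequence(n_occ) + rep.int(index$ptr[runs], n_occ)
  out <- tibble(chrom = index$occ_chrom[occ_idx],
                ref_pos = index$occ_pos[occ_idx],
                read_pos = rep.int(ih - 1L, n_occ),
                length = index$k)
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$chrom, .data$ref_pos, .data$read_pos)
}

#' Neighborhood distance bound for a read
#'
#' `d = floor(lam * read_len)`: the maximum displacement, on either axis,
#' between two anchors joined by an edge. Scaling with read length keeps
#' the bound proportional to the largest plausible aligned span; the
#' default multiplier 1.2 reflects the reference-to-read length ratio
#' expected under an indel-dominated error process.
#'
#' @param read_len Read length in bases.
#' @param lam Dimensionless multiplier (default 1.2).
#' @return Integer distance bound in bases.
#' @export
compute_d <- function(read_len, lam = 1.2) {
  stopifnot(read_len >= 1, lam > 0)
  as.integer(floor(lam * read_len))
}

#' Edge predicate of the anchor neighborhood graph
#'
#' `vi -> vj` is an edge iff both anchors sit on the same chromosome and
#' `vj` lies strictly forward of `vi` on BOTH the reference and the read
#' axis, with neither displacement exceeding `d`. Strict forward
#' displacement makes the relation a strict partial order, so the graph is
#' a DAG and a chain is automatically colinear.
#'
#' @param vi,vj One-row anchor tibbles (or lists) with `chrom`, `ref_pos`,
#'   `read_pos`.
#' @param d Distance bound from [compute_d()].
#' @return Logical.
#' @export
is_edge <- function(vi, vj, d) {
  dref <- vj$ref_pos - vi$ref_pos
  dread <- vj$read_pos - vi$read_pos
  vi$chrom == vj$chrom && dref > 0 && dref <= d && dread > 0 && dread <= d
}
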