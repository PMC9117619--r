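#' Build the k-mer occurrence index of a reference genome
#'
#' Every forward-strand k-mer of every chromosome is recorded at every
#' offset; k-mers containing `N` are skipped, and k-mers occurring more
#' than `freq_cap` times genome-wide are masked (dropped entirely) so that
#' high-copy repeats do not blow up the anchor graph. Occurrences are held
#' in a compressed sparse layout (sorted unique 2-bit codes plus offset
#' runs), so a query is one binary search. Reverse-strand mapping is
#' handled at the read level (the mapper also maps the reverse complement
#' of each read), not by indexing both strands.
#'
#' @param genome Tibble with columns `id`, `seq` (e.g. from
#'   [read_fasta()]).
#' @param k K-mer length in bases (8–26, default 15).
#' @param freq_cap Maximum occurrences stored per k-mer; beyond this the
#'   k-mer is masked (default 500).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 15L, freq_cap = 500L) {
  stopifnot(is.data.frame(genome), all(c("id", "seq") %in% names(genome)))
  k <- as.integer(k)
  if (k < 8L || k > 26L) stop("k must be in [8, 26]", call. = FALSE)
  if (nrow(genome) == 0L || all(nchar(genome$seq) < k))
    stop("no reference sequence of length >= k; index would be empty",
         call. = FALSE)
  codes <- vector("list", nrow(genome))
  poss <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    ci <- encode_kmers_cpp(genome$seq[i], k)
    keep <- which(!is.na(ci))
    codes[[i]] <- ci[keep]
    poss[[i]] <- keep - 1L # 0-based offsets
  }
  code <- unlist(codes, use.names = FALSE)
  pos <- unlist(poss, use.names = FALSE)
  chrom <- rep.int(seq_len(nrow(genome)),
                   vapply(codes, length, integer(1)))
  ord <- order(code, chrom, pos)
  code <- code[ord]; pos <- pos[ord]; chrom <- chrom[ord]
  # run-length over sorted codes -> occurrence table
  new_run <- c(TRUE, code[-1L] != code[-length(code)])
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  keep_run <- run_len <= freq_cap
  keep_occ <- keep_run[run_id]
  code <- code[keep_occ]; pos <- pos[keep_occ]; chrom <- chrom[keep_occ]
  uniq <- code[c(TRUE, code[-1L] != code[-length(code)])]
  ptr <- c(0L, cumsum(run_len[keep_run]))
  structure(list(k = k, freq_cap = as.integer(freq_cap),
                 codes = uniq, ptr = ptr,
                 occ_chrom = chrom, occ_pos = pos,
                 chrom_names = genome$id,
                 chrom_lengths = setNames(nchar(genome$seq), genome$id)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "| freq_cap =", x$freq_cap, "\n")
  cat("  ", length(x$chrom_names), "sequence(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp;",
      format(length(x$codes), big.mark = ","), "distinct k-mers,",
      format(length(x$occ_pos), big.mark = ","), "stored occurrences\n")
  invisible(x)
}

# binary-search a vector of (already encoded) k-mer codes; returns the
# index into idx$codes or NA
match_codes <- function(idx, codes) {
  hit <- findInterval(codes, idx$codes)
  ok <- hit > 0L & !is.na(codes)
  ok[ok] <- idx$codes[hit[ok]] == codes[ok]
  hit[!ok] <- NA_integer_
  hit
}

#' Look up one k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer Nucleotide string of length exactly `index$k`.
#' @return Tibble of occurrences (`chrom`, `pos`, 0-based), sorted by
#'   (chrom, pos); zero rows when the k-mer is absent, masked, or contains
#'   `N`.
#' @export
query_index <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(kmer) != index$k)
    stop("query length ", nchar(kmer), " != k = ", index$k, call. = FALSE)
  code <- encode_kmers_cpp(toupper(kmer), index$k)
  hit <- match_codes(index, code)
  if (is.na(hit))
    return(tibble(chrom = character(0), pos = integer(0)))
  sl <- (index$ptr[hit] + 1L):index$ptr[hit + 1L]
  out <- tibble(chrom = index$chrom_names[index$occ_chrom[sl]],
                pos = index$occ_pos[sl])
  dplyr::arrange(out, .data$chrom, .data$pos)
}
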