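#' Read sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Qualities,
#' masking and descriptions are not retained: the mapper is quality-blind.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq` (uppercase nucleotide string).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(tibble(id = character(0), seq = character(0)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(chartr("Uu", "Tt", as.character(set)))
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty id) in ", path, call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record '", ids[!nzchar(seqs)][1], "' in ",
         path, call. = FALSE)
  tibble(id = ids, seq = unname(seqs))
}

#' Read sequences from a FASTQ file
#'
#' A strict 4-line-per-record parser. Quality strings are checked for
#' length agreement with the sequence and then discarded — no stage of
#' the mapper uses base qualities.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L) return(tibble(id = character(0), seq = character(0)))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record near line ", length(lines), " in ", path,
         call. = FALSE)
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]; seq <- lines[i + 1L]; plus <- lines[i + 2L]; qual <- lines[i + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record at line ", (bad[1] - 1L) * 4L + 1L, " in ",
         path, call. = FALSE)
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism))
    stop("sequence/quality length mismatch at line ",
         (mism[1] - 1L) * 4L + 2L, " in ", path, call. = FALSE)
  tibble(id = sub("\\s.*$", "", substring(hdr, 2L)),
         seq = toupper(chartr("Uu", "Tt", seq)))
}

#' Auto-detect FASTA/FASTQ by first character and read it
#' @param path Path to a FASTA or FASTQ file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_seqs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- substring(readLines(path, n = 1L), 1L, 1L)
  if (length(first) == 0L) return(tibble(id = character(0), seq = character(0)))
  if (first == ">") read_fasta(path) else read_fastq(path)
}

#' Write sequences to FASTA
#' @param seqs Tibble with columns `id`, `seq`.
#' @param path Output path.
#' @param width Line-wrap width; `Inf` for single-line records.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    if (is.finite(width) && nchar(s) > width) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Write sequences to FASTQ with constant placeholder qualities
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(rbind(paste0("@", seqs$id), seqs$seq, "+",
                   vapply(nchar(seqs$seq),
                          function(n) strrep("I", n), character(1))), con)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Vectorised; `N` maps to `N`. The involution `rc(rc(s)) == s` holds for
#' every sequence over the `{A,C,G,T,N}` alphabet.
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Write alignment records as SAM 1.6
#'
#' Emits an `@HD`/`@SQ` header and one line per record. Internal 0-based
#' half-open coordinates are converted to SAM's 1-based `POS` here and
#' nowhere else. Mapped records carry FLAG 0 (forward) or 16 (reverse;
#' `SEQ` is the read as aligned, i.e. already reverse-complemented by the
#' mapper); unmapped reads carry FLAG 4, `POS` 0 and CIGAR `*`. CIGARs use
#' M/I/D only — mapped reads are end-to-end by construction, so no S/H
#' ever appears. An `NM` tag (edit distance) is included on mapped lines.
#'
#' @param alns Tibble of alignment records as produced by [map_reads()]
#'   (columns `read_id`, `mapped`, `chrom`, `strand`, `ref_start`,
#'   `ref_end`, `cigar`, `seq`, `n_mismatch`, `n_ins`, `n_del`).
#' @param ref Reference tibble (`id`, `seq`) used for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alns, ref, path) {
  mapped <- !is.na(alns$mapped) & alns$mapped
  unknown <- setdiff(unique(alns$chrom[mapped]), ref$id)
  if (length(unknown))
    stop("record chromosome(s) not in reference: ",
         paste(unknown, collapse = ","), call. = FALSE)
  for (i in which(mapped)) {
    cg <- cigar_parse(alns$cigar[i])
    if (cigar_query_len(cg$ops, cg$lens) != nchar(alns$seq[i]))
      stop("CIGAR query length disagrees with sequence for read ",
           alns$read_id[i], call. = FALSE)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$seq)),
           "@PG\tID:skelmap\tPN:skelmap")
  flag <- ifelse(mapped, ifelse(alns$strand == "-", 16L, 0L), 4L)
  nm <- alns$n_mismatch + alns$n_ins + alns$n_del
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                  alns$read_id, flag,
                  ifelse(mapped, alns$chrom, "*"),
                  ifelse(mapped, alns$ref_start + 1L, 0L),
                  ifelse(mapped, 60L, 0L),
                  ifelse(mapped, alns$cigar, "*"),
                  alns$seq,
                  ifelse(mapped, sprintf("\tNM:i:%d", as.integer(nm)), ""))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file back into an alignment tibble
#'
#' Minimal reader for the dialect [write_sam()] emits (single-end, M/I/D
#' CIGARs); sufficient for evaluating this mapper's own output.
#'
#' @param path Path to a SAM file.
#' @return Tibble with one row per record; unmapped rows have `NA`
#'   coordinates.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(tibble(read_id = character(0), mapped = logical(0),
                  chrom = character(0), strand = character(0),
                  ref_start = integer(0), ref_end = integer(0),
                  cigar = character(0), seq = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- vapply(f, length, integer(1))
  if (any(nfield < 11L))
    stop("SAM line with fewer than 11 fields at record ",
         which(nfield < 11L)[1], call. = FALSE)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- vapply(f, `[[`, "", 6L)
  ref_start <- as.integer(vapply(f, `[[`, "", 4L)) - 1L
  ref_len <- vapply(cigar, function(cg) {
    p <- cigar_parse(cg); as.integer(cigar_ref_len(p$ops, p$lens))
  }, integer(1), USE.NAMES = FALSE)
  tibble(read_id = vapply(f, `[[`, "", 1L),
         mapped = mapped,
         chrom = ifelse(mapped, vapply(f, `[[`, "", 3L), NA_character_),
         strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                         NA_character_),
         ref_start = ifelse(mapped, ref_start, NA_integer_),
         ref_end = ifelse(mapped, ref_start + ref_len, NA_integer_),
         cigar = ifelse(mapped, cigar, NA_character_),
         seq = vapply(f, `[[`, "", 10L))
}

#' Read / write per-read truth tables
#'
#' Tab-separated with columns `read_id`, `chrom`, `strand`, `ref_start`,
#' `ref_end`, `truth_cigar` (and any extra columns, preserved). For
#' reverse-strand reads the truth CIGAR describes the reverse-complemented
#' read laid on the forward reference, i.e. the same orientation a SAM
#' record uses.
#'
#' @param path Path to the TSV.
#' @return [read_truth()]: a tibble; [write_truth()]: `path`, invisibly.
#' @export
read_truth <- function(path) {
  tb <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("read_id", "chrom", "strand", "ref_start", "ref_end", "truth_cigar")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("truth file missing column(s): ", paste(miss, collapse = ","),
         call. = FALSE)
  tb
}

#' @rdname read_truth
#' @param truth Truth tibble.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write structural-variant truth tables
#'
#' Tab-separated with columns `sv_type` (`insertion`/`deletion`/
#' `inversion`), `chrom`, `bp_start`, `bp_end` (0-based half-open
#' breakpoint interval in ORIGINAL reference coordinates) and `size`.
#'
#' @param path Path to the TSV.
#' @return [read_sv_truth()]: a tibble; [write_sv_truth()]: `path`,
#'   invisibly.
#' @export
read_sv_truth <- function(path) {
  tb <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("sv_type", "chrom", "bp_start", "bp_end", "size")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("SV truth file missing column(s): ", paste(miss, collapse = ","),
         call. = FALSE)
  tb
}

#' @rdname read_sv_truth
#' @param svs SV tibble.
#' @export
write_sv_truth <- function(svs, path) {
  write.table(svs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
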