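ops_chr <- c("M", "I", "D")

# run-length CIGAR <-> string. Internally CIGARs travel as a list with
# integer `ops` (0=M, 1=I, 2=D) and `lens`; strings only at the SAM/TSV
# boundary.
cigar_string <- function(frag) {
  if (length(frag$ops) == 0L) return("*")
  paste0(frag$lens, ops_chr[frag$ops + 1L], collapse = "")
}

cigar_parse <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || cigar == "")
    return(list(ops = integer(0), lens = integer(0)))
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  op_c <- substring(toks, nchar(toks), nchar(toks))
  bad <- setdiff(unique(op_c), c("M", "I", "D", "S"))
  if (length(bad))
    stop("unsupported CIGAR op(s): ", paste(bad, collapse = ","), call. = FALSE)
  list(ops = c(M = 0L, I = 1L, D = 2L, S = 3L)[op_c],
       lens = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

# merge adjacent same-op runs and drop zero-length runs
cigar_canonical <- function(ops, lens) {
  keep <- lens > 0L
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lens <- as.integer(tapply(lens, grp, sum))
    ops <- ops[!duplicated(grp)]
  }
  list(ops = as.integer(unname(ops)), lens = as.integer(unname(lens)))
}

cigar_query_len <- function(ops, lens) sum(lens[ops %in% c(0L, 1L, 3L)])
cigar_ref_len <- function(ops, lens) sum(lens[ops %in% c(0L, 2L)])

# Reference offset (0-based) aligned to each query base; NA for bases the
# alignment does not place on the reference (I and S). Query bases are in
# alignment (reference-forward) orientation.
cigar_ref_positions <- function(cigar, ref_start) {
  cg <- if (is.list(cigar)) cigar else cigar_parse(cigar)
  n_q <- cigar_query_len(cg$ops, cg$lens)
  out <- rep(NA_real_, n_q)
  qi <- 0L
  rp <- ref_start
  for (r in seq_along(cg$ops)) {
    op <- cg$ops[r]; len <- cg$lens[r]
    if (op == 0L) {
      out[(qi + 1L):(qi + len)] <- rp + seq_len(len) - 1
      qi <- qi + len; rp <- rp + len
    } else if (op == 1L || op == 3L) {
      qi <- qi + len
    } else if (op == 2L) {
      rp <- rp + len
    }
  }
  out
}
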