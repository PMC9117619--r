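truth_row <- function(start, end, strand = "+", chrom = "chr1",
                      cigar = NULL, read_len = end - start) {
  tibble::tibble(read_id = "r", chrom = chrom, strand = strand,
                 ref_start = start, ref_end = end,
                 truth_cigar = cigar %||% paste0(end - start, "M"),
                 read_len = read_len)
}
aln_row <- function(start, end, strand = "+", chrom = "chr1",
                    cigar = NULL) {
  tibble::tibble(read_id = "r", mapped = TRUE, chrom = chrom,
                 strand = strand, ref_start = start, ref_end = end,
                 cigar = cigar %||% paste0(end - start, "M"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the correctly-mapped-read rule counts overlap, strand, and boundary", {
  tr <- truth_row(5000, 6000, read_len = 1000)
  expect_true(is_cmr(tr, aln_row(5050, 6000)))          # overlap 950 >= 900
  expect_false(is_cmr(tr, aln_row(5050, 6000, "-")))    # wrong strand
  expect_true(is_cmr(tr, aln_row(5100, 6000)))          # overlap exactly 900
  expect_false(is_cmr(tr, aln_row(5101, 6000)))         # 899 < 900
  expect_false(is_cmr(tr, aln_row(5050, 6000, chrom = "chr2")))
})

test_that("correctly-mapped-base counting matches a brute-force position walk", {
  # identical alignments: every M base is correct
  tr <- truth_row(100, 133, cigar = "10M5D10M2I8M", read_len = 30)
  al <- aln_row(100, 133, cigar = "10M5D10M2I8M")
  expect_equal(count_cmb(tr, al), 28L) # 30 query bases, 2 are I

  # a uniform 6-base shift beyond tol = 5 scores zero
  al6 <- aln_row(106, 139, cigar = "10M5D10M2I8M")
  expect_equal(count_cmb(tr, al6), 0L)
  # a 5-base shift is within tolerance
  al5 <- aln_row(105, 138, cigar = "10M5D10M2I8M")
  expect_equal(count_cmb(tr, al5), 28L)

  # random CIGAR pairs against a brute-force per-base comparison
  set.seed(71)
  rand_cigar <- function(qlen) {
    ops <- integer(0); lens <- integer(0); q <- 0L
    while (q < qlen) {
      op <- sample(0:2, 1, prob = c(0.7, 0.15, 0.15))
      len <- min(sample(1:4, 1), if (op != 2L) qlen - q else 3L)
      if (op != 2L) q <- q + len
      ops <- c(ops, op); lens <- c(lens, len)
    }
    cg <- skelmap:::cigar_canonical(ops, lens)
    list(str = skelmap:::cigar_string(cg), cg = cg)
  }
  for (rep in 1:40) {
    qlen <- sample(5:25, 1)
    c1 <- rand_cigar(qlen); c2 <- rand_cigar(qlen)
    s1 <- sample(0:50, 1); s2 <- sample(0:50, 1)
    tr <- truth_row(s1, s1 + skelmap:::cigar_ref_len(c1$cg$ops, c1$cg$lens),
                    cigar = c1$str, read_len = qlen)
    al <- aln_row(s2, s2 + skelmap:::cigar_ref_len(c2$cg$ops, c2$cg$lens),
                  cigar = c2$str)
    # brute force: position of each query base under each cigar
    pos_of <- function(cg, start) {
      out <- rep(NA_real_, qlen); qi <- 0L; rp <- start
      for (r in seq_along(cg$ops)) {
        for (x in seq_len(cg$lens[r])) {
          if (cg$ops[r] == 0L) { qi <- qi + 1L; out[qi] <- rp; rp <- rp + 1 }
          else if (cg$ops[r] == 1L) qi <- qi + 1L
          else rp <- rp + 1
        }
      }
      out
    }
    p1 <- pos_of(c1$cg, s1); p2 <- pos_of(c2$cg, s2)
    want <- sum(!is.na(p1) & !is.na(p2) & abs(p1 - p2) <= 5)
    expect_equal(count_cmb(tr, al, tol = 5L), want)
  }
})

test_that("aligned coverage reflects query-consuming non-clipped bases", {
  expect_equal(aligned_coverage("1000M", 1000), 1.0)
  expect_equal(aligned_coverage("100S900M", 1000), 0.9)
  expect_equal(aligned_coverage("450M10D50I500M", 1000), 1.0)
  expect_true(is.na(aligned_coverage(NA_character_, 1000)))
})

test_that("sensitivity and precision follow their definitions on a toy set", {
  # two reads of 100 bases; one mapped perfectly, one unmapped
  truth <- dplyr::bind_rows(
    truth_row(0, 100), truth_row(500, 600))
  truth$read_id <- c("a", "b")
  alns <- dplyr::bind_rows(
    aln_row(0, 100),
    tibble::tibble(read_id = "b", mapped = FALSE, chrom = NA,
                   strand = NA, ref_start = NA_integer_,
                   ref_end = NA_integer_, cigar = NA_character_))
  alns$read_id <- c("a", "b")
  ev <- evaluate_mapping(alns, truth)
  m <- glance(ev)
  expect_equal(m$n_cmr, 1L)
  expect_equal(m$n_cmb, 100)
  expect_equal(m$sensitivity_pct, 50)
  expect_equal(m$precision_pct, 100)
  expect_equal(m$aligned_coverage_pct, 100)
})

test_that("consecutiveness is monotone and thresholds are inclusive", {
  cov <- c(1, 1, 0.92, 0.80)
  cons <- consecutiveness(cov)
  expect_equal(unname(cons["c80"]), 100)
  expect_equal(unname(cons["c85"]), 75)
  expect_equal(unname(cons["c90"]), 75)
  expect_equal(unname(cons["c95"]), 50)
  expect_true(all(diff(cons) <= 0))
})

test_that("breakpoint spanning requires strict containment", {
  bp <- tibble::tibble(sv_type = "deletion", chrom = "chr1",
                       bp_start = 400L, bp_end = 410L)
  expect_true(sv_spanning(aln_row(100, 900), bp))
  expect_false(sv_spanning(aln_row(405, 900), bp))
  expect_false(sv_spanning(aln_row(100, 410), bp)) # boundary: strict >
  expect_false(sv_spanning(aln_row(400, 900), bp)) # boundary: strict <
  # monotone under interval extension
  expect_true(sv_spanning(aln_row(99, 901), bp))
})

test_that("agreement is reflexive and asymmetric", {
  a1 <- aln_row(1000, 3000)
  a2 <- aln_row(1000, 2000)
  expect_true(agreement(a1, a1))
  expect_true(agreement(a1, a2))   # a1 covers all of a2
  expect_false(agreement(a2, a1))  # a2 covers half of a1
  a3 <- aln_row(9000, 9500)
  expect_false(agreement(a1, a3))
  expect_false(agreement(a3, a1))
})

test_that("the alignment score recomputation matches hand arithmetic", {
  ref <- strrep("A", 50)
  perfect <- tibble::tibble(cigar = "20M", ref_start = 0L,
                            seq = strrep("A", 20))
  expect_equal(alignment_score(perfect, ref), 20)
  one_sub <- tibble::tibble(cigar = "20M", ref_start = 0L,
                            seq = paste0(strrep("A", 10), "C",
                                         strrep("A", 9)))
  expect_equal(alignment_score(one_sub, ref), 19 - 1)
  # 10M 3D 10M: 20 matches - (3 gap bases + 1 open)
  with_del <- tibble::tibble(cigar = "10M3D10M", ref_start = 0L,
                             seq = strrep("A", 20))
  expect_equal(alignment_score(with_del, ref), 20 - 4)
  # clipped bases cost -1 each without an open
  clipped <- tibble::tibble(cigar = "5S15M", ref_start = 0L,
                            seq = strrep("A", 20))
  expect_equal(alignment_score(clipped, ref), 15 - 5)
})
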