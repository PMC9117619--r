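frag_query_len <- function(fr) sum(fr$lens[fr$ops %in% c(0L, 1L)])
frag_ref_len <- function(fr) sum(fr$lens[fr$ops %in% c(0L, 2L)])

test_that("global alignment matches known small cases", {
  p <- aln_params()
  id <- nw_global("ACGT", "ACGT", p)
  expect_equal(id$score, 4)
  expect_equal(id$ops, 0L)
  expect_equal(id$lens, 4L)

  del <- nw_global("ACGT", "AGT", p)
  expect_equal(del$score, 2) # 3 matches - 1 query-side gap base
  expect_equal(frag_query_len(del), 4L)
  expect_equal(frag_ref_len(del), 3L)

  expect_equal(nw_global("", "", p)$score, 0)
  expect_equal(nw_global("ACG", "", p), list(ops = 1L, lens = 3L, score = -3))
  expect_equal(nw_global("", "ACG", p), list(ops = 2L, lens = 3L, score = -3))
})

test_that("all three aligners agree with an independent full DP and, on tiny strings, exhaustive recursion", {
  set.seed(51)
  p <- aln_params()
  for (i in 1:250) {
    q <- random_seq(sample(0:7, 1))
    t <- random_seq(sample(0:7, 1))
    g <- nw_global(q, t, p)
    s <- semi_global(q, t, p)
    expect_equal(g$score, oracle_align_score(q, t, "global"))
    if (nchar(q) > 0 && nchar(t) > 0)
      expect_equal(s$score, oracle_align_score(q, t, "semi"))
    # relaxation property and conservation
    expect_gte(s$score, g$score)
    expect_equal(frag_query_len(g), nchar(q))
    expect_equal(frag_ref_len(g), nchar(t))
    if (i <= 30) { # recursion oracle is exponential; spot-check
      expect_equal(g$score, oracle_align_recursive(q, t, "global"))
    }
  }
  # longer pairs against the full-matrix DP (exercises the band)
  for (i in 1:30) {
    q <- random_seq(sample(10:60, 1))
    t <- random_seq(sample(10:120, 1))
    expect_equal(nw_global(q, t, p)$score, oracle_align_score(q, t, "global"))
    expect_equal(semi_global(q, t, p)$score, oracle_align_score(q, t, "semi"))
  }
})

test_that("semi-global localises the query and reports overhangs", {
  p <- aln_params()
  s <- semi_global("ACGT", "TTTTACGTTTTT", p)
  expect_equal(s$score, 4)
  expect_equal(s$t_start, 4L)
  expect_equal(s$t_used, 4L)
  expect_equal(s$ops, 0L)
  # query == target: identical to global
  q <- random_seq(25)
  expect_equal(semi_global(q, q, p)$score, nw_global(q, q, p)$score)
})

test_that("gap classification partitions into exactly one category", {
  expect_equal(classify_gap(10, 12, mu = 2), "match")
  expect_equal(classify_gap(10, 50, mu = 2), "deletion")
  expect_equal(classify_gap(50, 10, mu = 2), "insertion")
  expect_equal(classify_gap(0, 0, mu = 2), "empty")
  expect_equal(classify_gap(0, 7, mu = 2), "deletion")
  expect_equal(classify_gap(7, 0, mu = 2), "insertion")
  # boundary: L(S_G) exactly (1+mu)*L(S_R) stays match (strict >)
  expect_equal(classify_gap(10, 30, mu = 2), "match")
  expect_equal(classify_gap(10, 31, mu = 2), "deletion")
  # all categories on a grid: exactly one label each
  grid <- expand.grid(lr = 0:12, lg = 0:12)
  cats <- classify_gap(grid$lr, grid$lg, mu = 2)
  expect_true(all(cats %in% c("empty", "match", "deletion", "insertion")))
  expect_equal(sum(cats == "empty"), 1L)
})

test_that("gap filling conserves both segments in every category", {
  set.seed(52)
  p <- aln_params()
  expect_equal(fill_gap("", "", "empty", p),
               list(ops = integer(0), lens = integer(0), score = 0))
  # deletion: 11 unmatched reference bases must come out as D
  del <- fill_gap("ACG", "ACGTTTTTTTTACG", "deletion", p)
  expect_equal(sum(del$lens[del$ops == 2L]), 11L)
  expect_equal(frag_query_len(del), 3L)
  expect_equal(frag_ref_len(del), 14L)
  # insertion mirrors with I runs
  ins <- fill_gap("ACGTTTTTTTTACG", "ACG", "insertion", p)
  expect_equal(sum(ins$lens[ins$ops == 1L]), 11L)
  expect_equal(frag_query_len(ins), 14L)
  expect_equal(frag_ref_len(ins), 3L)
  # random pairs in every category conserve
  for (i in 1:60) {
    lr <- sample(0:30, 1); lg <- sample(0:30, 1)
    sr <- random_seq(lr); sg <- random_seq(lg)
    cat <- classify_gap(lr, lg, mu = 2)
    fr <- fill_gap(sr, sg, cat, p)
    expect_equal(frag_query_len(fr), lr)
    expect_equal(frag_ref_len(fr), lg)
  }
})

test_that("skeleton partition yields n-1 inner pairs and reconstructs spans", {
  set.seed(53)
  ref <- random_seq(600)
  # seven non-overlapping anchors on one diagonal region
  skel <- tibble::tibble(chrom = 1L,
                         ref_pos = c(0L, 40L, 90L, 150L, 260L, 340L, 420L),
                         read_pos = c(0L, 38L, 85L, 148L, 250L, 335L, 410L),
                         length = 15L)
  read <- random_seq(440)
  part <- partition_gaps(skel, read, ref, mu = 2)
  expect_equal(nrow(part$blocks), 7L)
  expect_equal(nrow(part$gaps), 6L)
  # block + gap intervals tile the aligned span on both axes
  expect_equal(part$gaps$ref_start, part$blocks$ref_end[-7])
  expect_equal(part$gaps$ref_end, part$blocks$ref_start[-1])
  widths <- sum(part$blocks$ref_end - part$blocks$ref_start) +
    sum(part$gaps$ref_end - part$gaps$ref_start)
  expect_equal(widths, part$blocks$ref_end[7] - part$blocks$ref_start[1])

  # adjacent anchors at consecutive offsets merge into one block
  tight <- tibble::tibble(chrom = 1L, ref_pos = c(10L, 11L, 12L),
                          read_pos = c(5L, 6L, 7L), length = 15L)
  pt <- partition_gaps(tight, read, ref, mu = 2)
  expect_equal(nrow(pt$blocks), 1L)
  expect_equal(pt$blocks$ref_end - pt$blocks$ref_start, 17L)

  # overlapping anchors on different diagonals are trimmed, never negative
  cross <- tibble::tibble(chrom = 1L, ref_pos = c(10L, 20L),
                          read_pos = c(5L, 12L), length = 15L)
  pc <- partition_gaps(cross, read, ref, mu = 2)
  expect_true(all(pc$gaps$ref_end >= pc$gaps$ref_start))
  expect_true(all(pc$gaps$read_end >= pc$gaps$read_start))
})

test_that("boundary extension consumes the whole read and matches the free-end oracle", {
  set.seed(54)
  p <- aln_params()
  ref <- random_seq(2000)
  # skeleton block in the middle; suffix continues exactly -> all-M
  blocks <- tibble::tibble(ref_start = 500L, ref_end = 600L,
                           read_start = 100L, read_end = 200L)
  read <- paste0(substring(ref, 401, 500), substring(ref, 501, 600),
                 substring(ref, 601, 640))
  ext <- extend_boundaries(blocks, read, ref, p)
  expect_equal(ext$ref_start, 400L)
  expect_equal(ext$ref_end, 640L)
  expect_equal(ext$left$ops, 0L)
  expect_equal(ext$left$lens, 100L)
  expect_equal(ext$right$ops, 0L)
  expect_equal(ext$right$lens, 40L)

  # empty suffix -> empty fragment
  blocks2 <- tibble::tibble(ref_start = 0L, ref_end = 100L,
                            read_start = 0L, read_end = 100L)
  ext2 <- extend_boundaries(blocks2, substring(ref, 1, 100), ref, p)
  expect_equal(length(ext2$left$ops), 0L)
  expect_equal(length(ext2$right$ops), 0L)

  # random suffixes: score equals the full-DP oracle with free target end
  for (i in 1:25) {
    suf <- random_seq(20)
    readx <- paste0(substring(ref, 501, 600), suf)
    bl <- tibble::tibble(ref_start = 500L, ref_end = 600L,
                         read_start = 0L, read_end = 100L)
    extx <- extend_boundaries(bl, readx, ref, p)
    target <- substring(ref, 601, 640)
    expect_equal(extx$right$score,
                 oracle_align_score(suf, target, "extend"))
    expect_equal(frag_query_len(extx$right), 20L)
  }

  # window clipped at the chromosome end still consumes the whole suffix
  near_end <- tibble::tibble(ref_start = 1950L, ref_end = 1990L,
                             read_start = 0L, read_end = 40L)
  ready <- paste0(substring(ref, 1951, 1990), random_seq(50))
  exty <- extend_boundaries(near_end, ready, ref, p)
  expect_equal(frag_query_len(exty$right), 50L)
  expect_lte(exty$ref_end, 2000L)
})

test_that("assembled alignments are end-to-end and score-consistent", {
  set.seed(55)
  g <- tibble::tibble(id = "c0", seq = random_seq(20000))
  idx <- build_index(g)
  # error-free excision: perfect all-M record
  read <- substring(g$seq, 10001, 12000)
  anchors <- extract_anchors(idx, read)
  dp <- chain_scores(anchors, compute_d(2000), 1)
  skel <- refine_skeleton(backtrack_skeleton(dp), 2000)
  rec <- assemble_alignment(skel, read, g$seq)
  expect_equal(rec$ref_start, 10000L)
  expect_equal(rec$ref_end, 12000L)
  expect_equal(rec$cigar, "2000M")
  expect_equal(rec$score, 2000)

  # simulated noisy reads: conservation always holds
  sim <- simulate_reads(g, 15, c(1000, 3000), error_profile(), seed = 56)
  alns <- map_reads(sim$reads, idx, g, map_config())
  for (i in which(alns$mapped)) {
    cg <- skelmap:::cigar_parse(alns$cigar[i])
    expect_equal(skelmap:::cigar_query_len(cg$ops, cg$lens), alns$read_len[i])
    expect_equal(skelmap:::cigar_ref_len(cg$ops, cg$lens),
                 alns$ref_end[i] - alns$ref_start[i])
    expect_false(grepl("[SH]", alns$cigar[i]))
  }
})

test_that("a simulated 100 bp deletion shows up as one long D run", {
  set.seed(57)
  g <- generate_genome(8000, seed = 58)
  # read spans positions 2000..5000 of a genome whose 3000..3100 is deleted
  mut <- paste0(substring(g$seq, 1, 3000), substring(g$seq, 3101, 8000))
  read <- substring(mut, 2001, 4900)
  idx <- build_index(g)
  aln <- map_read(tibble::tibble(id = "d", seq = read), idx, g,
                  map_config())
  expect_true(aln$mapped)
  cg <- skelmap:::cigar_parse(aln$cigar)
  druns <- cg$lens[cg$ops == 2L]
  expect_equal(sum(druns >= 90), 1L)
  expect_lte(abs(max(druns) - 100L), 10L)
})
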