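test_that("genome simulation is seeded, annotated and repeat-faithful", {
  g1 <- simulate_genome(10000, 0, seed = 5)
  expect_equal(nchar(g1$chromosomes), 10000)
  expect_equal(nrow(g1$repeats), 0L)
  g2 <- simulate_genome(10000, 0, seed = 5)
  expect_identical(g1$chromosomes, g2$chromosomes)  # determinism

  g3 <- simulate_genome(100000, 2, 2000, 3, 0.02, seed = 9)
  expect_equal(nrow(g3$repeats), 6L)
  # copies of one family are ~ (1-d)^2 identical; check pairwise identity by
  # direct base comparison of the planted copies (no indels by construction)
  for (f in 1:2) {
    cps <- g3$repeats[g3$repeats$family == f, ]
    s <- substring(g3$chromosomes, cps$start + 1, cps$end)
    m <- mapply(function(a, b) {
      mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    }, s[1], s[2:3])
    expect_true(all(m >= 0.94))  # 2 x 2% divergence plus sampling noise
    expect_true(all(m <= 1.0))
  }
  # annotations within bounds and disjoint
  expect_true(all(g3$repeats$start >= 0 & g3$repeats$end <= 100000))
  o <- g3$repeats[order(g3$repeats$start), ]
  expect_true(all(diff(o$start) >= 2000))
})

test_that("long reads respect coverage, error rates and truth intervals", {
  g <- simulate_genome(100000, 0, seed = 2)
  # error-free reads are exact substrings (or reverse complements)
  lr0 <- simulate_long_reads(g, 3, 8000, 1000, error_model(0, 0, 0), seed = 2)
  for (i in seq_len(min(10, length(lr0$reads)))) {
    tr <- lr0$truth[i, ]
    src <- substr(g$chromosomes, tr$start + 1, tr$end)
    if (tr$strand == "-") src <- revcomp(src)
    expect_identical(lr0$reads$seq[i], src)
  }
  # coverage accounting within 2%
  lr <- simulate_long_reads(g, 30, 8000, 1000, error_model(), seed = 3)
  tot <- sum(nchar(lr$reads$seq))
  expect_gt(tot, 30 * 100000 * 0.98)
  expect_lt(tot, 30 * 100000 * 1.02)
  expect_true(all(nchar(lr$reads$seq) >= 900))  # min length (pre-error 1000)

  # substitution-only at 5%: identity to truth 95% +/- 0.5%
  lr5 <- simulate_long_reads(g, 2, 10000, 2000, error_model(0.05, 0, 0, 1),
                             seed = 4)
  ids <- vapply(seq_len(length(lr5$reads)), function(i) {
    tr <- lr5$truth[i, ]
    src <- substr(g$chromosomes, tr$start + 1, tr$end)
    if (tr$strand == "-") src <- revcomp(src)
    1 - mean(strsplit(lr5$reads$seq[i], "")[[1]] != strsplit(src, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.95), 0.005)
})

test_that("short pairs follow the requested insert distribution", {
  g <- simulate_genome(1e6, 0, seed = 6)
  sp <- simulate_short_pairs(g, 50, 150, 350, 0, seed = 6)
  expect_equal(length(sp$mate1), length(sp$mate2))
  # coverage 50x, 2x150 on 1 Mb -> ~166,667 pairs
  expect_lt(abs(length(sp$mate1) - 166667), 0.02 * 166667)
  # sd 0 -> all inserts equal the mean
  expect_true(all(sp$truth$insert == 350))
  # endpoints within the chromosome
  expect_true(all(sp$truth$start >= 0))
  expect_true(all(sp$truth$start + sp$truth$insert <= 1e6))
  # mate2 is the reverse complement of the fragment end
  i <- 1
  frag_end <- substr(g$chromosomes, sp$truth$start[i] + 350 - 150 + 1,
                     sp$truth$start[i] + 350)
  expect_identical(sp$mate2$seq[i], revcomp(frag_end))
})

test_that("draft contigs tile the genome and chimeras are recorded", {
  g <- simulate_genome(3e5, 0, seed = 8)
  d0 <- make_draft_contigs(g, 12, n_chimeras = 0, seed = 8)
  # tiling: concatenation in truth order reconstructs the chromosome
  expect_identical(paste0(d0$contigs$seq, collapse = ""), g$chromosomes)
  expect_equal(nrow(d0$chimeras), 0L)

  d2 <- make_draft_contigs(g, 12, n_chimeras = 2, seed = 8)
  expect_equal(nrow(d2$chimeras), 2L)
  expect_true(all(d2$chimeras$contig %in% d2$contigs$id))
  # junction flanked by loci >= 50 kb apart
  expect_true(all(abs(d2$chimeras$left_start - d2$chimeras$right_start)
                  >= 50000))
  # with gaps: total contig length is below genome length, pieces in order
  dg <- make_draft_contigs(g, 12, seed = 8, gap_min = 100, gap_max = 2000)
  expect_lt(sum(nchar(dg$contigs$seq)), 3e5)
  expect_true(all(diff(dg$truth$start) > 0))
})
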