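test_that("edit alignment is exact against an independent oracle", {
  expect_equal(edit_align("ACGT", "ACGT")$dist, 0L)
  expect_equal(edit_align("ACGT", "ACGT")$identity, 1.0)
  expect_equal(edit_align("ACGT", "AGT")$dist, 1L)
  # 500 random pairs up to 300 bp against base R's Levenshtein distance
  set.seed(111)
  for (i in 1:500) {
    a <- random_dna(sample(0:300, 1))
    b <- if (runif(1) < 0.5) random_dna(sample(0:300, 1)) else
      ssga:::cpp_inject_errors(a, 0.05, 0.03, 0.03, 1)
    got <- edit_align(a, b, band_frac = 1)   # full band: exact
    expect_equal(got$dist, as.integer(adist(a, b)))
    # the ops string reproduces both sequences and counts the distance
    ops <- strsplit(got$ops, "")[[1]]
    expect_equal(sum(ops %in% c("=", "X", "I")), nchar(a))
    expect_equal(sum(ops %in% c("=", "X", "D")), nchar(b))
    expect_equal(sum(ops %in% c("X", "I", "D")), got$dist)
  }
})

test_that("semi-global anchor alignment locates an embedded query", {
  set.seed(112)
  target <- random_dna(5000)
  q <- substr(target, 2001, 3000)
  ia <- ssga:::cpp_infix_align(q, target)
  expect_equal(ia$dist, 0L)
  expect_equal(ia$tstart, 2000L)
  expect_equal(ia$tend, 3000L)
  expect_equal(ia$identity, 1.0)
  # with errors, still lands in the right place
  qe <- ssga:::cpp_inject_errors(q, 0.03, 0.01, 0.01, 1)
  set.seed(112)
  ia2 <- ssga:::cpp_infix_align(qe, target)
  expect_lt(abs(ia2$tstart - 2000), 60)
  expect_gt(ia2$identity, 0.9)
})

test_that("read selection ranks by contributed pairs with deterministic ties", {
  mr <- data.frame(read = c(5L, 2L, 9L, 1L, 7L),
                   npairs = c(4L, 9L, 4L, 2L, 9L),
                   g_lo = 0L, g_hi = 0L, m1v = 2L)
  g <- manual_ssg(c(1000, 1000), c(10, 10),
                  data.frame(u = 2L, v = 3L, l = 10, sigma = 5, w = 28L),
                  mate_reads = list(mr))
  sel <- select_spanning_reads(g, 1L, n = 3L)
  expect_equal(sel$read, c(2L, 7L, 5L))      # ties by ascending read index
  expect_equal(nrow(select_spanning_reads(g, 1L, n = 20L)), 5L)
  # 30 reads -> exactly 20 returned
  mr30 <- data.frame(read = 1:30, npairs = 31 - (1:30), g_lo = 0L,
                     g_hi = 0L, m1v = 2L)
  g30 <- manual_ssg(c(1000, 1000), c(10, 10),
                    data.frame(u = 2L, v = 3L, l = 10, sigma = 5, w = 1L),
                    mate_reads = list(mr30))
  expect_equal(nrow(select_spanning_reads(g30, 1L)), 20L)
})

test_that("window consensus recovers the truth from noisy copies", {
  set.seed(113)
  truth <- random_dna(2600)
  # identical copies: consensus == template
  wc0 <- window_consensus(truth, rep(truth, 10))
  expect_identical(as.character(wc0), truth)
  expect_true(all(attr(wc0, "depth") == 11L))
  # template with 5% errors + 15 copies with 5% errors each: consensus
  # within 0.5% of truth
  tpl <- ssga:::cpp_inject_errors(truth, 0.02, 0.015, 0.015, 1.5)
  copies <- vapply(1:15, function(i)
    ssga:::cpp_inject_errors(truth, 0.02, 0.015, 0.015, 1.5), character(1))
  wc <- window_consensus(tpl, copies)
  d <- edit_align(as.character(wc), truth, band_frac = 0.3)$dist
  expect_lt(d / nchar(truth), 0.005)
  # a low-identity chunk is excluded from its window's consensus: corrupt
  # exactly window 3 (template coordinates 1001-1500) of one copy
  garbage <- paste0(substr(truth, 1, 1000), random_dna(500),
                    substr(truth, 1501, 2600))
  wcg <- window_consensus(truth, c(rep(truth, 3), garbage))
  dep <- attr(wcg, "depth")
  expect_equal(dep[3], 4L)                  # window 3 excludes the bad chunk
  expect_identical(as.character(wcg), truth)
})

test_that("gap filling reconstructs a known gap and anchors contig bases", {
  w <- two_contig_world(gap = 800, seed = 115)
  ps <- preset("ontraw")
  idx <- build_index(w$contigs, ps)
  sp <- default_spectrum(ps, 8000)
  mres <- map_synthetic_pairs(w$reads, idx, sp, ps)
  g <- build_ssg(w$contigs, mres)
  g <- mask_repeats(g)
  red <- transitive_reduce(g)
  g <- red$g
  mc <- matching_cover(g, min_weight = 2L)
  lines <- break_cycles_extract_lines(g, mc)
  expect_equal(length(lines), 1L)
  db <- build_read_db(lines, g, w$reads)
  fg <- fill_gaps(lines, db, g, w$contigs)
  expect_equal(nrow(fg$report), 1L)
  expect_equal(fg$report$status, "filled")
  # realized fill within 4 sigma of the true gap (error-free reads: exact)
  expect_lt(abs(fg$report$realized - w$gap),
            max(4 * fg$report$sigma, 25))
  # the line sequence equals the genome here (error-free world)
  expect_equal(unname(nchar(fg$sequences[1])), nchar(w$genome))
  expect_identical(fg$sequences[[1]], w$genome)
  # contig terminal bases appear verbatim (never rewritten)
  expect_true(grepl(substr(w$contigs$seq[1], 5501, 6000), fg$sequences[1],
                    fixed = TRUE))
})

test_that("negative gaps merge truly overlapping contigs", {
  set.seed(116)
  genome <- random_dna(12000)
  # contigs overlap by 300 bp
  c1 <- substr(genome, 1, 6300)
  c2 <- substr(genome, 6001, 12000)
  contigs <- seq_set(c("A", "B"), c(c1, c2))
  starts <- round(seq(0, 12000 - 9000, length.out = 8))
  reads <- seq_set(sprintf("r%d", 1:8),
                   substring(genome, starts + 1, starts + 9000))
  ps <- preset("ontraw")
  idx <- build_index(contigs, ps)
  sp <- default_spectrum(ps, 9000)
  mres <- map_synthetic_pairs(reads, idx, sp, ps)
  g <- build_ssg(contigs, mres)
  g <- mask_repeats(g)
  g <- transitive_reduce(g)$g
  mc <- matching_cover(g, min_weight = 2L)
  lines <- break_cycles_extract_lines(g, mc)
  db <- build_read_db(lines, g, reads)
  fg <- fill_gaps(lines, db, g, contigs)
  expect_lt(fg$report$realized[1], 0)
  expect_identical(fg$sequences[[1]], genome)   # merged without inserted bases
})
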