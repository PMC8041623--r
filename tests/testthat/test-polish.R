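test_that("expected identity interpolates linearly over depth 1..20", {
  expect_equal(expected_identity(1), 0.80)
  expect_equal(expected_identity(20), 0.99)
  expect_equal(expected_identity(100), 0.99)   # clamped above
  expect_equal(expected_identity(0), 0.80)     # clamped below
  expect_equal(expected_identity(10), 0.80 + 9 * 0.19 / 19)
  expect_equal(expected_identity(10), 0.89)
  d <- seq(1, 20, by = 0.5)
  expect_true(all(diff(expected_identity(d)) > 0))  # monotone
})

# world: three unique contigs A,R',B where the true gap interior between A and
# B is a repeat whose (error-free) copy exists as a leftover contig; the
# consensus over the gap is error-bearing, so splicing the contig improves it
polish_world <- function(seed = 121, gap_repeat = 1500, err = 0.04) {
  set.seed(seed)
  left <- random_dna(8000)
  rep_unit <- random_dna(gap_repeat)
  right <- random_dna(8000)
  genome <- paste0(left, rep_unit, right)
  contigs <- seq_set(c("A", "B", "R"),
                     c(left, right, rep_unit))
  starts <- round(seq(0, nchar(genome) - 11000, length.out = 14))
  reads0 <- substring(genome, starts + 1, starts + 11000)
  reads <- vapply(reads0, function(s)
    ssga:::cpp_inject_errors(s, err / 2, err / 4, err / 4, 1.5), character(1))
  list(genome = genome,
       contigs = contigs,
       reads = seq_set(sprintf("r%02d", seq_along(reads)), unname(reads)),
       rep_unit = rep_unit)
}

run_to_fill <- function(w, min_weight = 2L) {
  ps <- preset("ontraw")
  idx <- build_index(w$contigs, ps)
  sp <- default_spectrum(ps, 11000)
  mres <- map_synthetic_pairs(w$reads, idx, sp, ps)
  g <- build_ssg(w$contigs, mres)
  g <- mask_repeats(g)
  red <- transitive_reduce(g)
  g <- red$g
  mc <- matching_cover(g, min_weight = min_weight)
  lines <- break_cycles_extract_lines(g, mc)
  db <- build_read_db(lines, g, w$reads)
  fg <- fill_gaps(lines, db, g, w$contigs)
  list(g = g, lines = lines, fg = fg)
}

test_that("the graph polisher splices a matching leftover contig", {
  w <- polish_world()
  st <- run_to_fill(w)
  # the A--B line was filled across the repeat interior
  main_line <- which(vapply(st$lines, function(l) length(l$contigs) > 1,
                            logical(1)))
  expect_gte(length(main_line), 1L)
  before <- st$fg$sequences
  gp <- graph_polish(before, st$fg$fills, st$g, st$lines, w$contigs)
  # distance of the spliced region to truth should not increase; when the
  # repeat contig is spliced, the interior becomes exact
  if (nrow(gp$report) && any(gp$report$action == "spliced")) {
    expect_true(any(gp$used))
    d_before <- edit_align(before[[1]], w$genome, band_frac = 0.3)$dist
    d_after <- edit_align(gp$sequences[[1]], w$genome, band_frac = 0.3)$dist
    expect_lte(d_after, d_before)
  }
  # a contig is rejected when its identity is below the expected threshold
  f <- st$fg$fills[[1]]
  f$depth <- rep(20L, length(f$depth))   # demands 99% identity
  fills_hi <- st$fg$fills; fills_hi[[1]] <- f
  junk <- ssga:::cpp_inject_errors(w$rep_unit, 0.10, 0.02, 0.02, 1)
  out <- ssga:::try_splice_contig(before, fills_hi, 1L, junk,
                                  polish_params())
  expect_null(out)
})

test_that("the alignment polisher lays out hits greedily and splices", {
  w <- polish_world(seed = 122)
  st <- run_to_fill(w)
  gp <- graph_polish(st$fg$sequences, st$fg$fills, st$g, st$lines, w$contigs)
  # reset usage so the alignment polisher gets a chance at the repeat contig
  used0 <- rep(FALSE, nrow(st$g$contigs))
  ap <- alignment_polish(st$fg$sequences, st$fg$fills, st$g, st$lines,
                         w$contigs, used0)
  expect_true(nrow(ap$report) >= 1)
  expect_true(all(ap$report$action == "spliced_aln"))
  # spliced interior contains the repeat contig verbatim
  expect_true(any(vapply(ap$sequences, function(s)
    grepl(w$rep_unit, s, fixed = TRUE), logical(1))))
})

test_that("final assembly emits lines plus long unused leftovers only", {
  lines <- list(list(contigs = c(1L, 2L), orient = c(1L, 1L),
                     mate_edges = 1L, gaps = 100, starts = c(0, 1100),
                     length = 2100),
                list(contigs = 3L, orient = 1L, mate_edges = integer(0),
                     gaps = numeric(0), starts = 0, length = 4000),
                list(contigs = 4L, orient = 1L, mate_edges = integer(0),
                     gaps = numeric(0), starts = 0, length = 6000),
                list(contigs = 5L, orient = 1L, mate_edges = integer(0),
                     gaps = numeric(0), starts = 0, length = 6000))
  g <- manual_ssg(c(1000, 1000, 4000, 6000, 6000), rep(10, 5),
                  data.frame(u = 2L, v = 3L, l = 100, sigma = 10, w = 9L))
  contigs <- seq_set(sprintf("c%02d", 1:5),
                     vapply(c(1000, 1000, 4000, 6000, 6000), random_dna,
                            character(1)))
  seqs <- c(L1 = paste0(contigs$seq[1], strrep("N", 100), contigs$seq[2]),
            L2 = contigs$seq[3], L3 = contigs$seq[4], L4 = contigs$seq[5])
  used <- c(FALSE, FALSE, FALSE, FALSE, TRUE)  # c05 consumed by polishing
  asm <- emit_assembly(seqs, lines, g, contigs, used)
  expect_equal(asm$id[1], "ssga-L1")           # the multi-contig line
  expect_true("c04" %in% asm$id)               # 6 kb unused: included
  expect_false("c03" %in% asm$id)              # 4 kb: too short
  expect_false("c05" %in% asm$id)              # consumed: not re-emitted
})
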