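test_that("matching cover picks heavy edges and respects vertex disjointness", {
  # two contigs, one mate edge w=6: matched, ratio 1
  m1 <- data.frame(u = 2L, v = 3L, l = 10, sigma = 5, w = 6L)
  g1 <- manual_ssg(c(1000, 1000), c(10, 10), m1)
  g1$mate$removed <- FALSE
  mc1 <- matching_cover(g1)
  expect_equal(mc1$edges, 1L)
  expect_equal(mc1$ratio, 1)
  # vertex with competing edges w=5 and w=9: the heavier is matched
  m2 <- data.frame(u = c(2L, 2L), v = c(3L, 5L), l = c(10, 10),
                   sigma = c(5, 5), w = c(5L, 9L))
  g2 <- manual_ssg(rep(1000, 3), rep(10, 3), m2)
  g2$mate$removed <- c(FALSE, FALSE)
  mc2 <- matching_cover(g2)
  expect_equal(mc2$edges, 2L)
  expect_equal(mc2$w_matched, 9)
  # weight threshold and repeat masking exclude edges
  g3 <- g2
  g3$contigs$repeat_flag[3] <- TRUE
  mc3 <- matching_cover(g3)
  expect_equal(mc3$edges, 1L)          # w=9 touches the repeat contig
  mc4 <- matching_cover(g2, min_weight = 6L)
  expect_equal(mc4$edges, 2L)          # w=5 below threshold
})

test_that("matching weight reaches the exhaustive optimum on random graphs", {
  set.seed(91)
  worst <- 1
  for (rep in 1:200) {
    nc <- sample(3:10, 1)
    ne <- sample(2:12, 1)
    mate <- data.frame(u = sample(2L * nc, ne, replace = TRUE),
                       v = sample(2L * nc, ne, replace = TRUE))
    mate <- mate[v_contig(mate$u) != v_contig(mate$v), , drop = FALSE]
    mate <- mate[!duplicated(paste(pmin(mate$u, mate$v),
                                   pmax(mate$u, mate$v))), , drop = FALSE]
    if (nrow(mate) == 0) next
    mate$l <- 100; mate$sigma <- 50
    mate$w <- sample(5:50, nrow(mate), replace = TRUE)
    g <- manual_ssg(rep(1000, nc), rep(10, nc), mate)
    g$mate$removed <- rep(FALSE, nrow(mate))
    mc <- matching_cover(g)
    opt <- brute_matching(mate$u, mate$v, mate$w)
    expect_gte(mc$w_matched + 1e-9, (2 / 3) * opt)
    worst <- min(worst, mc$w_matched / opt)
    # components here are small, so the solver is exact
    expect_equal(mc$w_matched, opt)
    # vertex disjointness
    vs <- c(g$mate$u[mc$edges], g$mate$v[mc$edges])
    expect_false(any(duplicated(vs)))
  }
  expect_gte(worst, 2 / 3)
})

test_that("greedy fallback stays above half of the exact optimum", {
  set.seed(92)
  for (rep in 1:30) {
    nc <- sample(4:8, 1)
    ne <- sample(3:10, 1)
    mate <- data.frame(u = sample(2L * nc, ne, replace = TRUE),
                       v = sample(2L * nc, ne, replace = TRUE))
    mate <- mate[v_contig(mate$u) != v_contig(mate$v), , drop = FALSE]
    if (nrow(mate) == 0) next
    mate$l <- 100; mate$sigma <- 50
    mate$w <- sample(5:50, nrow(mate), replace = TRUE)
    g <- manual_ssg(rep(1000, nc), rep(10, nc), mate)
    g$mate$removed <- rep(FALSE, nrow(mate))
    mcg <- matching_cover(g, greedy_only = TRUE)
    opt <- brute_matching(mate$u, mate$v, mate$w)
    expect_gte(mcg$w_matched + 1e-9, 0.5 * opt)
  }
})

test_that("cycles are destroyed at the lowest-weight mate edge", {
  # 3 contigs matched into a triangle: head->tail chain closing on itself
  mate <- data.frame(u = c(2L, 4L, 6L), v = c(3L, 5L, 1L),
                     l = c(10, 10, 10), sigma = c(5, 5, 5),
                     w = c(5L, 6L, 7L))
  g <- manual_ssg(rep(1000, 3), rep(10, 3), mate)
  g$mate$removed <- rep(FALSE, 3)
  mc <- list(edges = 1:3)
  lines <- break_cycles_extract_lines(g, mc)
  expect_equal(length(lines), 1L)
  expect_equal(length(lines[[1]]$contigs), 3L)
  expect_equal(sort(lines[[1]]$mate_edges), c(2L, 3L))  # w=5 removed
  # acyclic matching: path components preserved; singleton contig is a line
  mate2 <- data.frame(u = 2L, v = 3L, l = 10, sigma = 5, w = 9L)
  g2 <- manual_ssg(rep(1000, 3), rep(10, 3), mate2)
  g2$mate$removed <- FALSE
  lines2 <- break_cycles_extract_lines(g2, list(edges = 1L))
  expect_equal(length(lines2), 2L)
  sizes <- sort(vapply(lines2, function(l) length(l$contigs), integer(1)))
  expect_equal(sizes, c(1L, 2L))
  # every contig appears in exactly one line
  allc <- unlist(lapply(lines2, `[[`, "contigs"))
  expect_equal(sort(allc), 1:3)
})

test_that("line orientation and coordinates follow the traversal", {
  # A:head -> B:tail and B:head -> C:tail: all forward
  mate <- data.frame(u = c(2L, 4L), v = c(3L, 5L), l = c(100, 200),
                     sigma = c(5, 5), w = c(9L, 9L))
  g <- manual_ssg(c(1000, 2000, 3000), rep(10, 3), mate)
  g$mate$removed <- c(FALSE, FALSE)
  ln <- break_cycles_extract_lines(g, list(edges = 1:2))[[1]]
  expect_equal(ln$contigs, 1:3)
  expect_equal(ln$orient, rep(1L, 3))
  expect_equal(ln$starts, c(0, 1100, 3300))
  expect_equal(ln$length, 6300)
  # a flipped middle contig: A:head -> B:head means B is reversed
  mate2 <- data.frame(u = c(2L, 3L), v = c(4L, 5L), l = c(100, 200),
                      sigma = c(5, 5), w = c(9L, 9L))
  g2 <- manual_ssg(c(1000, 2000, 3000), rep(10, 3), mate2)
  g2$mate$removed <- c(FALSE, FALSE)
  ln2 <- break_cycles_extract_lines(g2, list(edges = 1:2))[[1]]
  expect_equal(ln2$orient[2], -1L)
})

test_that("unsupported joins are split only below the support threshold", {
  # two contigs joined by an edge supported by 3 short reads, no long-read
  # physical coverage: split (3 < 4)
  mk <- function(nsup, read_lens) {
    mr <- list(data.frame(read = seq_len(nsup), npairs = 1L,
                          g_lo = 100L, g_hi = 200L, m1v = 2L))
    g <- manual_ssg(c(30000, 30000), c(10, 10),
                    data.frame(u = 2L, v = 3L, l = 100, sigma = 10, w = 6L),
                    mate_reads = mr, read_ids = sprintf("r%d", seq_len(nsup)),
                    read_lens = read_lens)
    g$mate$removed <- FALSE
    g
  }
  g_weak <- mk(3L, rep(5000L, 3))
  lines <- break_cycles_extract_lines(g_weak, list(edges = 1L))
  val <- validate_backbone(lines, g_weak,
                           transitive_reduce(g_weak)$path_db)
  expect_equal(length(val$lines), 2L)          # split
  expect_true(any(val$report$split))
  # same join but spanned by >= min_support reads: kept
  g_ok <- mk(6L, rep(5000L, 6))
  lines_ok <- break_cycles_extract_lines(g_ok, list(edges = 1L))
  val_ok <- validate_backbone(lines_ok, g_ok,
                              transitive_reduce(g_ok)$path_db)
  expect_equal(length(val_ok$lines), 1L)
  # joins covered by long reads (>= 20 kb) are never suspicious
  g_long <- mk(3L, rep(25000L, 3))
  lines_l <- break_cycles_extract_lines(g_long, list(edges = 1L))
  val_l <- validate_backbone(lines_l, g_long,
                             transitive_reduce(g_long)$path_db)
  expect_equal(length(val_l$lines), 1L)
})
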