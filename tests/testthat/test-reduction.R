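test_that("repeat masking uses the longest-contig coverage proxy", {
  mate <- data.frame(u = 2L, v = 3L, l = 100, sigma = 50, w = 10L)
  lens <- c(50000, rep(8000, 8), 3000)
  cov <- c(30, rep(30, 8), 50)
  g <- manual_ssg(lens, cov, mate)
  gm <- mask_repeats(g)
  expect_equal(attr(gm, "u_bar"), 30)          # longest 10% = 1 contig
  expect_true(gm$contigs$repeat_flag[10])      # 50 > 45
  # boundary: exactly 1.5 * u_bar is NOT masked (strict >)
  cov2 <- cov; cov2[10] <- 45
  gm2 <- mask_repeats(manual_ssg(lens, cov2, mate))
  expect_false(any(gm2$contigs$repeat_flag))
  # uniform coverage: nothing masked
  gm3 <- mask_repeats(manual_ssg(lens, rep(30, 10), mate))
  expect_false(any(gm3$contigs$repeat_flag))
})

test_that("biconnected decomposition matches brute force on small graphs", {
  # triangle: one component
  mate_t <- data.frame(u = c(2L, 4L, 6L), v = c(3L, 5L, 1L),
                       l = c(10, 10, 10), sigma = c(5, 5, 5), w = c(1L, 1L, 1L))
  g_t <- manual_ssg(rep(100, 3), rep(10, 3), mate_t)
  bc_t <- ssg_biconnected(g_t)
  expect_equal(length(unique(c(bc_t$contig_comp, bc_t$mate_comp))), 1L)
  # path of three contigs: each edge its own component
  mate_p <- data.frame(u = c(2L, 4L), v = c(3L, 5L), l = c(10, 10),
                       sigma = c(5, 5), w = c(1L, 1L))
  g_p <- manual_ssg(rep(100, 3), rep(10, 3), mate_p)
  bc_p <- ssg_biconnected(g_p)
  expect_equal(length(unique(c(bc_p$contig_comp, bc_p$mate_comp))), 5L)
  # random graphs <= 12 vertices: articulation vertices equal brute force
  set.seed(71)
  for (rep in 1:15) {
    nc <- sample(3:6, 1)
    ne <- sample(2:8, 1)
    mate <- unique(data.frame(
      u = sample(2L * nc, ne, replace = TRUE),
      v = sample(2L * nc, ne, replace = TRUE)))
    mate <- mate[v_contig(mate$u) != v_contig(mate$v), , drop = FALSE]
    if (nrow(mate) == 0) next
    mate$l <- 10; mate$sigma <- 5; mate$w <- 1L
    g <- manual_ssg(rep(100, nc), rep(10, nc), mate)
    got <- sort(ssg_biconnected(g)$articulation)
    el <- rbind(cbind(v_tail(seq_len(nc)), v_head(seq_len(nc))),
                cbind(mate$u, mate$v))
    expect_equal(got, sort(brute_articulation(el, 2L * nc)))
  }
})

# the three-contig chain with a long transitive edge: the toy reduction case
chain_fixture <- function(l_long = 2100, labels_long = c(1L, 2L),
                          labels_short = list(c(1L, 2L), c(1L, 2L))) {
  mate <- data.frame(u = c(2L, 4L, 2L), v = c(3L, 5L, 5L),
                     l = c(50, 50, l_long), sigma = c(20, 20, 60),
                     w = c(4L, 5L, 3L))
  mr <- list(
    data.frame(read = labels_short[[1]],
               npairs = rep(2L, length(labels_short[[1]])),
               g_lo = 0L, g_hi = 0L, m1v = 2L),
    data.frame(read = labels_short[[2]],
               npairs = rep(2L, length(labels_short[[2]])),
               g_lo = 0L, g_hi = 0L, m1v = 4L),
    data.frame(read = labels_long, npairs = rep(1L, length(labels_long)),
               g_lo = 0L, g_hi = 0L, m1v = 2L))
  manual_ssg(rep(2000, 3), rep(10, 3), mate, mate_reads = mr,
             contig_labels = rep(list(1:2), 3))
}

test_that("a length-coherent labeled long edge reduces onto the chain", {
  g <- chain_fixture()   # l(P) = 50 + 2000 + 50 = 2100 = l(e3)
  red <- transitive_reduce(g)
  expect_true(red$g$mate$removed[3])
  # weights of the path edges incremented by w(e)
  expect_equal(red$g$mate$w[1], 4L + 3L)
  expect_equal(red$g$mate$w[2], 5L + 3L)
  expect_equal(nrow(red$path_db), 1L)
  expect_equal(red$path_db$edge, 3L)
  expect_equal(sort(red$path_db$mate_edges[[1]]), c(1L, 2L))
  # support conserved: the removed edge's weight lives on in every path
  # edge, so the remaining total grows by w(e) * (path edges - 1)
  expect_equal(sum(red$g$mate$w[!red$g$mate$removed]),
               (4L + 5L + 3L) + 3L * (2L - 1L))
})

test_that("reduction respects the length tolerance and the label subset rule", {
  # path length off by more than 4 max(sigma): not reduced
  g_far <- chain_fixture(l_long = 2500)
  red_far <- transitive_reduce(g_far)
  expect_false(any(red_far$g$mate$removed))
  expect_equal(nrow(red_far$path_db), 0L)
  # F(e) not a subset of a path edge's labels: not reduced
  g_lab <- chain_fixture(labels_long = c(1L, 2L),
                         labels_short = list(c(1L, 2L), 1L))
  red_lab <- transitive_reduce(g_lab)
  expect_false(any(red_lab$g$mate$removed))
  # equal label sets allowed (subset read non-strictly)
  g_eq <- chain_fixture(labels_long = c(1L, 2L))
  expect_true(transitive_reduce(g_eq)$g$mate$removed[3])
  # graph with no transitive edges: unchanged
  mate <- data.frame(u = 2L, v = 3L, l = 100, sigma = 50, w = 5L)
  g0 <- manual_ssg(c(1000, 1000), c(10, 10), mate)
  red0 <- transitive_reduce(g0)
  expect_false(any(red0$g$mate$removed))
})

test_that("weight is conserved on random reducible fixtures", {
  set.seed(81)
  for (rep in 1:10) {
    nc <- sample(4:7, 1)
    # chain of contigs with adjacent edges, plus random skip edges
    adj <- data.frame(u = v_head(seq_len(nc - 1)), v = v_tail(2:nc),
                      l = 50, sigma = 20,
                      w = sample(3:9, nc - 1, replace = TRUE))
    nskip <- sample(1:3, 1)
    from <- sample(seq_len(nc - 2), nskip, replace = TRUE)
    skip <- data.frame(u = v_head(from), v = v_tail(from + 2L),
                       l = 50 + 2000 + 50, sigma = 60,
                       w = sample(1:5, nskip, replace = TRUE))
    mate <- rbind(adj, skip)
    g <- manual_ssg(rep(2000, nc), rep(10, nc), mate,
                    contig_labels = rep(list(1L), nc))
    tot <- sum(g$mate$w)
    red <- transitive_reduce(g)
    transferred <- if (nrow(red$path_db)) {
      sum(g$mate$w[red$path_db$edge] * (red$path_db$n_edges - 1L))
    } else 0L
    # exact bookkeeping of the weight transfer; in particular no support
    # is ever lost by a reduction
    expect_equal(sum(red$g$mate$w[!red$g$mate$removed]), tot + transferred)
    expect_gte(sum(red$g$mate$w[!red$g$mate$removed]), tot)
    # contig edges never removed, masked edges never traversed (structural)
    expect_equal(nrow(red$g$contigs), nc)
  }
})
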