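test_that("homopolymer compression collapses runs with a monotone map", {
  r <- compress_homopolymers("AAACCGT")
  expect_equal(r$seq, "ACGT")
  expect_equal(r$map, c(0L, 3L, 5L, 6L))
  r2 <- compress_homopolymers("ACGT")
  expect_equal(r2$seq, "ACGT")
  expect_equal(r2$map, 0:3)
  r3 <- compress_homopolymers("")
  expect_equal(r3$seq, "")
  expect_equal(length(r3$map), 0L)
})

# brute-force minimizer oracle: per window of w consecutive k-mers, pick the
# minimum canonical hash (independent R reimplementation)
brute_minimizers <- function(seq, w, k) {
  n <- nchar(seq)
  if (n < k) return(data.frame(hash = numeric(), pos = integer()))
  kmers <- substring(seq, 1:(n - k + 1), k:(n))
  hashes <- vapply(kmers, function(km) {
    h <- extract_minimizers(km, 1, k)  # single k-mer: its own hash
    h$hash[1]
  }, numeric(1))
  win <- min(w, length(hashes))
  sel <- unique(unlist(lapply(seq_len(length(hashes) - win + 1), function(i) {
    i + which.min(hashes[i:(i + win - 1)]) - 1L
  })))
  data.frame(hash = unname(hashes[sel]), pos = sel - 1L)
}

test_that("minimizer selection equals a brute-force window scan", {
  expect_equal(nrow(extract_minimizers("ACGTT", 5, 6)), 0L)  # seq shorter than k
  m1 <- extract_minimizers("ACGTACGTAC", 1, 3)
  expect_equal(m1$pos, 0:7)                                  # w=1: every k-mer
  m2 <- extract_minimizers("ACGTACGTAC", 3, 10)
  expect_equal(nrow(m2), 1L)                                 # len == k
  for (seed in 1:5) {
    s <- random_dna(80, seed)
    got <- extract_minimizers(s, 3, 3)
    exp <- brute_minimizers(s, 3, 3)
    expect_equal(got$pos, exp$pos)
    expect_equal(got$hash, exp$hash)
  }
  # also the quoted toy case
  expect_equal(extract_minimizers("ACGTACGTAC", 3, 3)$pos,
               brute_minimizers("ACGTACGTAC", 3, 3)$pos)
})

test_that("index construction checks ids and counts occurrences", {
  ps <- preset("shortr")
  expect_error(build_index(seq_set(c("a", "a"), c("ACGT", "ACGT")), ps),
               "duplicate")
  t1 <- random_dna(2000, 21)
  idx2 <- build_index(seq_set(c("x", "y"), c(t1, t1)), ps)
  info <- ssga:::cpp_index_info(idx2$ptr)
  expect_true(all(info$occ_counts %% 2 == 0))  # identical targets: all even
})

test_that("self-mapping recovers position, strand and full coverage", {
  ps <- preset("shortr")
  t1 <- random_dna(5000, 31)
  idx <- build_index(seq_set("t", t1), ps)
  a <- map_sequence(t1, idx)
  expect_equal(a$target, "t")
  expect_equal(a$pos, 0L)
  expect_equal(a$strand, "+")
  expect_equal(a$mapq, 60L)
  expect_gt(a$covered, 0.95)
  # reverse complement: strand flips, position mirrors to the same interval
  b <- map_sequence(revcomp(t1), idx)
  expect_equal(b$strand, "-")
  expect_lt(b$pos, 50L)
})

test_that("error-free reads map near truth; repeats force mapq 0", {
  set.seed(77)
  g <- simulate_genome(50000, 0, seed = 77)
  ps <- preset("ontraw")
  idx <- build_index(seq_set("chr", g$chromosomes), ps)
  lr <- simulate_long_reads(g, 1.5, 3000, 1000, error_model(0, 0, 0),
                            seed = 77)
  # trim to 250-bp synthetic-mate-sized queries from each read start
  q <- substring(lr$reads$seq, 1, 250)
  a <- map_sequence(seq_set(lr$reads$id, q), idx, ps)
  truth_start <- ifelse(lr$truth$strand == "+", lr$truth$start,
                        lr$truth$end - 250L)
  okpos <- abs(a$pos - truth_start) <= 50
  expect_gte(mean(okpos & !is.na(a$target)), 0.99)

  # exact two-copy repeat: the best and second-best chains tie
  rep_unit <- random_dna(1000, 5)
  genome2 <- paste0(random_dna(3000, 6), rep_unit, random_dna(3000, 7),
                    rep_unit, random_dna(3000, 8))
  idx2 <- build_index(seq_set("chr2", genome2), ps)
  probe <- substr(rep_unit, 300, 549)
  a2 <- map_sequence(probe, idx2, ps)
  expect_equal(a2$mapq, 0L)

  # zero shared minimizers: unmapped
  a3 <- map_sequence(strrep("A", 250), idx2, ps)
  expect_true(is.na(a3$target) || a3$covered < 0.2)
})

test_that("pair filters reject at the documented strict thresholds", {
  # construct a fake map result path through map_pair by building a world
  # where thresholds can be dialed: use the pure filter logic
  ps <- preset("shortr")
  ok <- function(mapq1, mapq2, cov1, cov2, p = ps) {
    a <- list(target = "t", mapq = mapq1, covered = cov1)
    b <- list(target = "t", mapq = mapq2, covered = cov2)
    pass <- function(x) !is.na(x$target) && x$mapq > p$min_mapq &&
      x$covered > p$min_cov
    pass(a) && pass(b)
  }
  expect_true(ok(31, 45, 0.6, 0.9))    # both strictly above
  expect_false(ok(30, 45, 0.6, 0.9))   # mapq exactly 30 rejected
  expect_false(ok(31, 45, 0.5, 0.9))   # coverage exactly 50% rejected
  psyn <- preset("ontraw")
  expect_false(ok(60, 60, 0.65, 0.9, psyn))  # exactly 65% rejected
  expect_true(ok(41, 41, 0.66, 0.9, psyn))

  # end-to-end: mates from one fragment are accepted by map_pair
  set.seed(12)
  genome <- random_dna(20000)
  contig <- seq_set("c", genome)
  idx <- build_index(contig, ps)
  m1 <- substr(genome, 1001, 1150)
  m2 <- revcomp(substr(genome, 1201, 1350))
  mp <- map_pair(seq_set("p", m1), seq_set("p", m2), idx, ps)
  expect_true(mp$accept[1])
  expect_equal(mp$aln1$strand, "+")
  expect_equal(mp$aln2$strand, "-")
})

test_that("chain scores equal a brute-force dynamic program", {
  # brute-force longest chain with strictly increasing q and t
  brute_chain <- function(q, t) {
    o <- order(q, -t)
    q <- q[o]; t <- t[o]
    n <- length(q)
    best <- rep(1L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (q[j] < q[i] && t[j] < t[i] && best[j] + 1L > best[i]) {
          best[i] <- best[j] + 1L
        }
      }
    }
    if (n == 0) 0L else max(best)
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    q <- sample.int(300, n, replace = TRUE)
    t <- sample.int(300, n, replace = TRUE)
    expect_equal(ssga:::cpp_chain_score(q, t), brute_chain(q, t))
  }
})

test_that("mapping is invariant under reverse complement of the query", {
  set.seed(13)
  g <- random_dna(30000)
  ps <- preset("ontraw")
  idx <- build_index(seq_set("t", g), ps)
  for (st in c(2000, 11000, 25000)) {
    q <- substr(g, st, st + 249)
    a <- map_sequence(q, idx, ps)
    b <- map_sequence(revcomp(q), idx, ps)
    expect_equal(a$target, b$target)
    expect_equal(a$strand, "+")
    expect_equal(b$strand, "-")
    expect_lt(abs(a$pos - b$pos), 30)   # mirrored interval, anchor slop
    expect_equal(a$mapq, b$mapq)
  }
})
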