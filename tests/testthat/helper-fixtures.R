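# shared fixtures: all generated in code, seeded

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny two-contig world with a known gap, plus error-free reads spanning it
two_contig_world <- function(gap = 800, ctg_len = 6000, n_reads = 12,
                             read_len = 9000, seed = 42) {
  set.seed(seed)
  genome <- random_dna(2 * ctg_len + gap)
  c1 <- substr(genome, 1, ctg_len)
  c2 <- substr(genome, ctg_len + gap + 1, 2 * ctg_len + gap)
  starts <- round(seq(0, nchar(genome) - read_len, length.out = n_reads))
  reads <- substring(genome, starts + 1, starts + read_len)
  list(genome = genome,
       contigs = seq_set(c("A", "B"), c(c1, c2)),
       reads = seq_set(sprintf("r%02d", seq_len(n_reads)), reads),
       gap = gap)
}

# build an ssg by hand from edge tables (for graph-algorithm tests)
manual_ssg <- function(contig_len, cov, mate, mate_reads = NULL,
                       contig_labels = NULL, read_ids = NULL,
                       read_lens = NULL) {
  n <- length(contig_len)
  ctg <- data.frame(id = sprintf("c%02d", seq_len(n)), len = contig_len,
                    cov = cov, repeat_flag = FALSE, stringsAsFactors = FALSE)
  mate$id <- seq_len(nrow(mate))
  if (is.null(mate_reads)) {
    mate_reads <- lapply(seq_len(nrow(mate)), function(i)
      data.frame(read = 1L, npairs = mate$w[i], g_lo = 0L, g_hi = 0L,
                 m1v = mate$u[i]))
  }
  if (is.null(contig_labels)) {
    allreads <- sort(unique(unlist(lapply(mate_reads, `[[`, "read"))))
    contig_labels <- rep(list(allreads), n)
  }
  structure(list(contigs = ctg, contig_labels = contig_labels,
                 mate = mate, mate_reads = mate_reads,
                 reads = read_ids, read_lens = read_lens,
                 spectrum = NULL, n_accepted_inter = sum(mate$w)),
            class = "ssg")
}

expect_same_seqset <- function(a, b) {
  expect_equal(a$id, b$id)
  expect_equal(a$seq, b$seq)
  expect_equal(is.null(a$qual), is.null(b$qual))
  if (!is.null(a$qual)) expect_equal(a$qual, b$qual)
}

# identity of a demo assembly to its simulated truth: every multi-contig line
# is located on the genome via the draft-contig truth table and compared by
# banded edit distance; returns identity over the covered bases and the
# covered fraction of the genome
assembly_identity <- function(demo) {
  genome <- demo$genome$chromosomes[1]
  truth <- demo$drafts$truth
  res <- demo$result
  tot_dist <- 0
  tot_cov <- 0
  line_of <- attr(res$assembly, "line_index")
  for (rec in which(!is.na(line_of))) {
    ln <- res$lines[[line_of[rec]]]
    ids <- res$ssg$contigs$id[ln$contigs]
    tr <- truth[match(ids, truth$contig), ]
    if (any(is.na(tr$start))) next
    a <- min(tr$start); b <- max(tr$end)
    sq <- res$assembly$seq[rec]
    if (tr$start[1] > tr$start[nrow(tr)]) sq <- revcomp(sq)
    ref <- substr(genome, a + 1, b)
    band <- max(64L, abs(nchar(ref) - nchar(sq)) + 50L,
                as.integer(0.05 * nchar(ref)))
    d <- ssga:::cpp_edit_dist_banded(sq, ref, band)
    tot_dist <- tot_dist + d
    tot_cov <- tot_cov + (b - a)
  }
  list(identity = 1 - tot_dist / tot_cov,
       covered = tot_cov / nchar(genome))
}
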