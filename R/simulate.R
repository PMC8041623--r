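#' Simulate a genome with planted repeat families
#'
#' Generates a uniform-random chromosome and plants `n_repeat_families`
#' families of mutated repeat copies at disjoint uniformly drawn loci. Each
#' copy is derived from the family consensus by per-base substitution at rate
#' `divergence`, so two copies of one family are about
#' `(1 - divergence)^2` identical. All randomness flows through `seed`;
#' identical arguments and seed give a bit-identical genome.
#'
#' @param length total genome length in bp (single chromosome).
#' @param n_repeat_families number of repeat families to plant (0 = none).
#' @param repeat_len length of each repeat copy in bp.
#' @param copies_per_family copies planted per family.
#' @param divergence per-base substitution rate applied independently to each
#'   planted copy.
#' @param seed integer RNG seed.
#' @return object of class `sim_genome`: list with `chromosomes` (character
#'   vector), `repeats` (data.frame chrom/start/end/family, 0-based
#'   half-open), and `seed`.
#' @export
simulate_genome <- function(length, n_repeat_families = 0L, repeat_len = 2000L,
                            copies_per_family = 3L, divergence = 0.02,
                            seed = 1L) {
  stopifnot(length > 0)
  set.seed(seed)
  chrom <- cpp_random_dna(as.integer(length))
  ann <- data.frame(chrom = integer(), start = integer(), end = integer(),
                    family = integer())
  if (n_repeat_families > 0) {
    total_rep <- n_repeat_families * copies_per_family * repeat_len
    if (total_rep > 0.5 * length) {
      warning("planted repeats exceed 50% of genome length")
    }
    n_cop <- n_repeat_families * copies_per_family
    # disjoint placement by rejection sampling
    starts <- integer(0)
    tries <- 0L
    while (base::length(starts) < n_cop) {
      cand <- sample.int(length - repeat_len, 1L) - 1L
      if (!any(abs(cand - starts) < repeat_len)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_cop) {
        stop("cannot place ", n_cop, " disjoint repeat copies of ",
             repeat_len, " bp in ", length, " bp")
      }
    }
    fam_seq <- vapply(seq_len(n_repeat_families), function(f)
      cpp_random_dna(as.integer(repeat_len)), character(1))
    k <- 0L
    for (f in seq_len(n_repeat_families)) {
      for (cp in seq_len(copies_per_family)) {
        k <- k + 1L
        copy <- cpp_mutate_subs(fam_seq[f], divergence)
        substr(chrom, starts[k] + 1L, starts[k] + repeat_len) <- copy
        ann <- rbind(ann, data.frame(chrom = 1L, start = starts[k],
                                     end = starts[k] + repeat_len,
                                     family = f))
      }
    }
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(chromosomes = chrom, repeats = ann, seed = seed),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("sim_genome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bp,", nrow(x$repeats), "repeat copies\n")
  invisible(x)
}

#' Error model for simulated long reads
#'
#' Per-base substitution/insertion/deletion probabilities, with indel rates
#' multiplied by `homopolymer_bias` inside homopolymer runs of length >= 3
#' (the dominant error mode of raw nanopore-like data).
#'
#' @param sub_rate,ins_rate,del_rate per-base probabilities, each in [0, 0.2].
#' @param homopolymer_bias indel-rate multiplier (>= 1) in homopolymer runs.
#' @return object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.015,
                        homopolymer_bias = 1.5) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) stop("error rates must be in [0, 0.2]")
  if (homopolymer_bias < 1) stop("homopolymer_bias must be >= 1")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, homopolymer_bias = homopolymer_bias),
            class = "error_model")
}

#' Simulate long reads from a genome
#'
#' Read lengths follow a log-normal distribution truncated below at
#' `length_min` with the requested mean; reads are drawn uniformly from both
#' strands until total bases reach `coverage` times the genome length (within
#' 2%). Errors are injected per the [error_model]; the truth table records
#' the error-free source interval of every read.
#'
#' @param genome a [simulate_genome] result.
#' @param coverage requested fold coverage (> 0).
#' @param length_mean mean read length in bp.
#' @param length_min minimum read length in bp (>= 1000).
#' @param em an [error_model].
#' @param seed integer RNG seed.
#' @return list with `reads` (a [seq_set]) and `truth` (data.frame read,
#'   chrom, start, end, strand; 0-based half-open on the forward strand).
#' @export
simulate_long_reads <- function(genome, coverage, length_mean = 15000,
                                length_min = 1000, em = error_model(),
                                seed = 1L) {
  if (coverage <= 0) stop("coverage must be positive")
  stopifnot(length_min >= 1000, length_mean > length_min)
  set.seed(seed + 1L)
  glen <- nchar(genome$chromosomes[1])
  target_bases <- coverage * glen
  # log-normal with sdlog 0.5; adjust meanlog so the truncated mean ~ mean
  sdlog <- 0.5
  meanlog <- log(length_mean) - sdlog^2 / 2
  ids <- character(0); seqs <- character(0)
  truth <- list()
  tot <- 0; i <- 0L
  while (tot < target_bases * 0.995) {
    L <- round(stats::rlnorm(1, meanlog, sdlog))
    if (L < length_min) next
    if (L > glen) L <- glen
    start <- sample.int(glen - L + 1L, 1L) - 1L
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    src <- substr(genome$chromosomes[1], start + 1L, start + L)
    if (strand == "-") src <- revcomp(src)
    rd <- cpp_inject_errors(src, em$sub_rate, em$ins_rate, em$del_rate,
                            em$homopolymer_bias)
    i <- i + 1L
    ids[i] <- sprintf("lr%06d", i)
    seqs[i] <- rd
    truth[[i]] <- data.frame(read = ids[i], chrom = 1L, start = start,
                             end = start + L, strand = strand)
    tot <- tot + nchar(rd)
  }
  list(reads = seq_set(ids, seqs), truth = do.call(rbind, truth))
}

#' Simulate short paired-end reads (forward-reverse)
#'
#' Insert sizes are Normal(`insert_mean`, `insert_sd`) truncated at
#' `2 * read_len`; pairs are drawn uniformly; mate 2 is the reverse
#' complement of the fragment end. Reads are error-free: draft-contig
#' correctness, not short-read error, is what downstream stages exercise.
#'
#' @param genome a [simulate_genome] result.
#' @param coverage fold base coverage of the pairs.
#' @param read_len mate length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp);
#'   `insert_mean > 2 * read_len` required.
#' @param seed integer RNG seed.
#' @return list with `mate1` and `mate2` (both [seq_set]) and `truth`
#'   (data.frame pair, start, insert).
#' @export
simulate_short_pairs <- function(genome, coverage, read_len = 150,
                                 insert_mean = 350, insert_sd = 35,
                                 seed = 1L) {
  if (insert_mean <= 2 * read_len) stop("insert_mean must exceed 2*read_len")
  set.seed(seed + 2L)
  glen <- nchar(genome$chromosomes[1])
  npairs <- round(coverage * glen / (2 * read_len))
  ins <- round(stats::rnorm(npairs, insert_mean, insert_sd))
  ins <- pmax(ins, 2L * read_len)
  start <- vapply(ins, function(d) sample.int(glen - d + 1L, 1L) - 1L,
                  integer(1))
  m1 <- substring(genome$chromosomes[1], start + 1L, start + read_len)
  m2 <- revcomp(substring(genome$chromosomes[1], start + ins - read_len + 1L,
                          start + ins))
  ids <- sprintf("sp%07d", seq_len(npairs))
  list(mate1 = seq_set(ids, m1), mate2 = seq_set(ids, m2),
       truth = data.frame(pair = ids, start = start, insert = ins))
}

#' Cut a genome into draft contigs, optionally with chimeras and gaps
#'
#' The genome is cut at `n_breaks` random positions. With `gap_max > 0` an
#' interval of `uniform(gap_min, gap_max)` bp is deleted at each break,
#' emulating the sequence a short-read assembler loses at repeats and
#' low-coverage loci; with the default 0 the contigs tile the genome exactly.
#' `n_chimeras` contigs are then formed by concatenating two non-adjacent
#' fragments whose source loci are at least 50 kb apart; the junction
#' coordinate within each chimeric contig is recorded.
#'
#' @param genome a [simulate_genome] result.
#' @param n_breaks number of random cut positions.
#' @param n_chimeras number of chimeric contigs to fabricate.
#' @param seed integer RNG seed.
#' @param gap_min,gap_max deleted-gap size range per break (bp).
#' @param min_len drop resulting fragments shorter than this.
#' @return list with `contigs` (a [seq_set]), `truth` (data.frame contig,
#'   start, end: source interval of each non-chimeric contig, in genome
#'   order) and `chimeras` (data.frame contig, junction, left_start,
#'   right_start).
#' @export
make_draft_contigs <- function(genome, n_breaks, n_chimeras = 0L, seed = 1L,
                               gap_min = 0L, gap_max = 0L, min_len = 200L) {
  set.seed(seed + 3L)
  glen <- nchar(genome$chromosomes[1])
  breaks <- sort(sample.int(glen - 1L, n_breaks))
  gaps <- if (gap_max > 0) {
    round(stats::runif(n_breaks, gap_min, gap_max))
  } else rep(0L, n_breaks)
  starts <- c(0L, breaks + gaps)
  ends <- c(breaks, glen)
  keep <- ends - starts >= min_len & ends <= glen
  starts <- starts[keep]; ends <- ends[keep]
  frag <- substring(genome$chromosomes[1], starts + 1L, ends)
  ids <- sprintf("ctg%04d", seq_along(frag))
  chim <- data.frame(contig = character(), junction = integer(),
                     left_start = integer(), right_start = integer())
  drop <- integer(0)
  if (n_chimeras > 0) {
    nfrag <- length(frag)
    if (nfrag < 2 * n_chimeras) stop("not enough fragments for chimeras")
    avail <- seq_len(nfrag)
    for (ci in seq_len(n_chimeras)) {
      ok <- FALSE
      for (t in seq_len(2000)) {
        ab <- sample(avail, 2L)
        if (abs(starts[ab[1]] - starts[ab[2]]) >= 50000 &&
            abs(ab[1] - ab[2]) > 1) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot find fragment pair >= 50 kb apart for chimera")
      avail <- setdiff(avail, ab)
      a <- ab[1]; b <- ab[2]
      newid <- sprintf("chim%02d", ci)
      chim <- rbind(chim, data.frame(contig = newid,
                                     junction = nchar(frag[a]),
                                     left_start = starts[a],
                                     right_start = starts[b]))
      frag[a] <- paste0(frag[a], frag[b])
      ids[a] <- newid
      drop <- c(drop, b)
    }
  }
  keep2 <- setdiff(seq_along(frag), drop)
  truth <- data.frame(contig = ids[keep2], start = starts[keep2],
                      end = ends[keep2])
  rownames(truth) <- NULL
  list(contigs = seq_set(ids[keep2], frag[keep2]), truth = truth,
       chimeras = chim)
}
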