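#' Pseudo-alignment presets
#'
#' Technology presets controlling minimizer geometry and pair-acceptance
#' filters. `shortr` (paired short reads) uses (10,21)-minimizers and rejects
#' a pair when either mate has mapping quality <= 30 or covers <= 50% of its
#' bases. The synthetic-pair presets (`ontlon`, `ontraw`, `pacraw`, `pacccs`)
#' use (5,20)-minimizers, 250-bp synthetic mates, and reject at mapping
#' quality <= 40 or coverage <= 65%; `pacraw` additionally applies
#' homopolymer compression before k-mer extraction.
#'
#' @param name one of `"shortr"`, `"ontlon"`, `"ontraw"`, `"pacraw"`,
#'   `"pacccs"`.
#' @return a list of class `preset` with fields `name`, `w`, `k`, `hpc`,
#'   `min_mapq`, `min_cov`, `synthetic_read_len` (NA for shortr), `max_occ`.
#' @export
preset <- function(name = c("shortr", "ontlon", "ontraw", "pacraw", "pacccs")) {
  name <- match.arg(name)
  p <- switch(name,
    shortr = list(w = 10L, k = 21L, hpc = FALSE, min_mapq = 30L,
                  min_cov = 0.50, synthetic_read_len = NA_integer_),
    ontlon = list(w = 5L, k = 20L, hpc = FALSE, min_mapq = 40L,
                  min_cov = 0.65, synthetic_read_len = 250L),
    ontraw = list(w = 5L, k = 20L, hpc = FALSE, min_mapq = 40L,
                  min_cov = 0.65, synthetic_read_len = 250L),
    pacraw = list(w = 5L, k = 20L, hpc = TRUE, min_mapq = 40L,
                  min_cov = 0.65, synthetic_read_len = 250L),
    pacccs = list(w = 5L, k = 20L, hpc = FALSE, min_mapq = 40L,
                  min_cov = 0.65, synthetic_read_len = 250L))
  p$name <- name
  p$max_occ <- 500L  # minimizers more frequent than this are skipped at query
  class(p) <- "preset"
  p
}

#' Homopolymer compression
#'
#' Collapses maximal single-base runs to one base and returns the (monotone)
#' 0-based map from compressed positions back to run starts in the original.
#'
#' @param seq a nucleotide string.
#' @return list with `seq` (compressed string) and `map` (integer vector,
#'   0-based original position of each compressed base).
#' @export
compress_homopolymers <- function(seq) {
  cpp_compress_hp(seq)
}

#' Extract canonical (w,k)-minimizers
#'
#' K-mers are 2-bit packed, the canonical form (minimum of the k-mer and its
#' reverse complement) is hashed with an invertible 64-bit integer mix, and
#' in each window of `w` consecutive k-mers the minimum-hash k-mer is
#' selected. Sequences shorter than `k` yield an empty set.
#'
#' @param seq a nucleotide string.
#' @param w window size in k-mer positions.
#' @param k k-mer length.
#' @return data.frame with columns `hash`, `pos` (0-based), `strand`
#'   (0 = canonical is the forward k-mer).
#' @export
extract_minimizers <- function(seq, w, k) {
  cpp_minimizers(seq, as.integer(w), as.integer(k))
}

#' Build a minimizer index over target sequences
#'
#' @param targets a [seq_set] of target sequences (unique ids).
#' @param preset a [preset] controlling (w, k, hpc).
#' @return a `min_index` handle used by [map_sequence] / [map_pair].
#' @export
build_index <- function(targets, preset) {
  if (anyDuplicated(targets$id)) {
    stop("duplicate target id: ", targets$id[duplicated(targets$id)][1])
  }
  ptr <- cpp_build_index(targets$id, targets$seq, preset$w, preset$k,
                         preset$hpc, preset$max_occ)
  structure(list(ptr = ptr, ids = targets$id, lens = seq_lengths(targets),
                 preset = preset),
            class = "min_index")
}

#' @export
print.min_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat(sprintf("min_index: %d targets, (%d,%d)-minimizers%s, %d distinct\n",
              info$n_targets, info$w, info$k,
              if (info$hpc) " (hpc)" else "", info$n_distinct_minimizers))
  invisible(x)
}

check_geometry <- function(idx, preset) {
  p <- idx$preset
  if (p$w != preset$w || p$k != preset$k || p$hpc != preset$hpc) {
    stop("index built with (", p$w, ",", p$k, ",hpc=", p$hpc,
         ") queried with (", preset$w, ",", preset$k, ",hpc=", preset$hpc, ")")
  }
}

#' Map sequences against a minimizer index
#'
#' Shared minimizers between query and targets become anchors; per
#' (target, strand) the best co-linear chain is the longest strictly
#' increasing subsequence over target positions. Mapping quality is
#' `round(60 * (1 - s2/s1))` for best and second-best chain scores (capped at
#' 60), so a strong secondary chain drives the quality to 0. `covered` is the
#' chained-anchor k-mer footprint divided by query length.
#'
#' @param reads a [seq_set] (or character vector) of queries.
#' @param idx a [build_index] result.
#' @param preset the [preset] the index was built with (geometry re-checked).
#' @return data.frame with one row per query: `qname`, `target` (id, NA when
#'   unmapped), `pos` (0-based), `strand` (`"+"`/`"-"`), `mapq`, `covered`,
#'   `n_anchors`.
#' @export
map_sequence <- function(reads, idx, preset = idx$preset) {
  check_geometry(idx, preset)
  seqs <- if (inherits(reads, "seq_set")) reads$seq else as.character(reads)
  qn <- if (inherits(reads, "seq_set")) reads$id else
    sprintf("q%d", seq_along(seqs))
  m <- cpp_map_batch(seqs, idx$ptr)
  data.frame(qname = qn,
             target = ifelse(is.na(m$target), NA_character_,
                             idx$ids[m$target]),
             pos = m$pos,
             strand = ifelse(is.na(m$strand), NA_character_,
                             c("+", "-")[m$strand + 1L]),
             mapq = m$mapq, covered = m$covered, n_anchors = m$n_anchors,
             stringsAsFactors = FALSE)
}

#' Map a mate pair and apply the pair-acceptance filter
#'
#' Both mates are mapped independently; the pair is accepted iff both map
#' and each mate has mapping quality strictly greater than the preset
#' threshold (30 for `shortr`, 40 for synthetic presets) and covers strictly
#' more than the preset fraction of its bases (0.50 / 0.65).
#'
#' @param mate1,mate2 [seq_set]s of equal length (mate2 as sequenced, i.e.
#'   reverse-complemented fragment ends).
#' @param idx a [build_index] result.
#' @param preset the [preset] in force.
#' @return list with `aln1`, `aln2` (as [map_sequence]) and `accept`
#'   (logical vector, pair-level).
#' @export
map_pair <- function(mate1, mate2, idx, preset = idx$preset) {
  a1 <- map_sequence(mate1, idx, preset)
  a2 <- map_sequence(mate2, idx, preset)
  ok <- function(a) !is.na(a$target) & a$mapq > preset$min_mapq &
    a$covered > preset$min_cov
  list(aln1 = a1, aln2 = a2, accept = ok(a1) & ok(a2))
}
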