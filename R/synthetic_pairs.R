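# Synthetic mate-pair libraries: the fixed insert-size schedule spans dense
# sub-10-kb steps and decade steps above, 24 entries from 0.5 kb to 200 kb.
SPECTRUM_SCHEDULE <- c(500, 1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000,
                       9000, 10000, 15000, 20000, 30000, 40000, 50000, 60000,
                       70000, 80000, 90000, 100000, 120000, 150000, 200000)
SPECTRUM_EXT <- c(300000, 400000, 500000)

#' Default spectrum of synthetic mate-pair libraries
#'
#' For ultralong nanopore input (`ontlon`) the full 24-library schedule from
#' 0.5 kb to 200 kb is used, optionally extended to 300/400/500 kb when the
#' read-length N50 reaches 100 kb. For all other presets the schedule is
#' truncated at the largest insert not exceeding twice the N50. Per-library
#' sigma is `max(50, 0.10 * insert)`.
#'
#' @param preset a [preset].
#' @param read_length_n50 long-read length N50 in bp (> 500).
#' @param sigma_frac fraction of the insert used as the library sd.
#' @return object of class `spectrum`: data.frame with columns `insert`,
#'   `sigma`, plus attributes `mate_len` (250) and `step` (150).
#' @export
default_spectrum <- function(preset, read_length_n50, sigma_frac = 0.10) {
  if (read_length_n50 <= 500) stop("read length N50 must exceed 500 bp")
  if (preset$name == "ontlon") {
    ins <- SPECTRUM_SCHEDULE
    if (read_length_n50 >= 100000) ins <- c(ins, SPECTRUM_EXT)
  } else {
    ins <- SPECTRUM_SCHEDULE[SPECTRUM_SCHEDULE <= 2 * read_length_n50]
    if (length(ins) == 0) ins <- SPECTRUM_SCHEDULE[1]
  }
  sp <- data.frame(insert = as.integer(ins),
                   sigma = pmax(50, sigma_frac * ins))
  attr(sp, "mate_len") <- 250L
  attr(sp, "step") <- 150L
  class(sp) <- c("spectrum", "data.frame")
  sp
}

#' Extract synthetic mate pairs from one long read
#'
#' For each library insert size d not exceeding the read length, 250-bp
#' mates are cut at offsets 0, 150, 300, ... while `offset + d` fits in the
#' read; mate 1 is the forward substring at the offset and mate 2 the
#' reverse complement of the 250 bp ending at `offset + d`
#' (forward-reverse orientation). Pair names encode
#' `readid|offset|insert|library`, the labeling channel the scaffolding
#' graph consumes.
#'
#' @param read a single-record [seq_set] (or one string).
#' @param spectrum a [default_spectrum] result.
#' @return data.frame with columns `read`, `offset`, `insert`, `lib`,
#'   `mate1`, `mate2`, `inner_start`, `inner_end` (0-based read coordinates
#'   of the span between the mates).
#' @export
extract_synthetic_pairs <- function(read, spectrum) {
  if (inherits(read, "seq_set")) {
    rid <- read$id[1]; rs <- read$seq[1]
  } else {
    rid <- "read"; rs <- as.character(read)[1]
  }
  L <- nchar(rs)
  ml <- attr(spectrum, "mate_len")
  step <- attr(spectrum, "step")
  out <- list()
  for (j in seq_len(nrow(spectrum))) {
    d <- spectrum$insert[j]
    if (d > L) next
    offs <- seq(0L, L - d, by = step)
    out[[j]] <- data.frame(
      read = rid, offset = offs, insert = d, lib = j,
      mate1 = substring(rs, offs + 1L, offs + ml),
      mate2 = revcomp(substring(rs, offs + d - ml + 1L, offs + d)),
      inner_start = offs + ml, inner_end = offs + d - ml)
  }
  if (length(out) == 0) {
    return(data.frame(read = character(), offset = integer(),
                      insert = integer(), lib = integer(),
                      mate1 = character(), mate2 = character(),
                      inner_start = integer(), inner_end = integer()))
  }
  do.call(rbind, out)
}

#' Extract and map synthetic pairs for a batch of long reads
#'
#' Fused extraction + pseudo-alignment: every synthetic pair of every library
#' is cut from the read, both mates are mapped against the contig index and
#' the pair-acceptance filter (mapping quality strictly above the preset
#' threshold, coverage strictly above the preset fraction, both mates) is
#' applied. Inter-contig pairs are returned in the orientation-normalized
#' frame used by the scaffolding graph; same-contig pairs contribute only to
#' per-library distance statistics and coverage.
#'
#' @param reads a [seq_set] of long reads.
#' @param idx contig [build_index] (synthetic preset geometry).
#' @param spectrum a [default_spectrum] result.
#' @param preset the synthetic [preset] in force.
#' @return list with `pairs` (data.frame read/offset/lib/c1/v1/pos1/c2/v2/
#'   pos2/g1/g2, indices 1-based into reads and contigs), `covbases`
#'   (mapped synthetic-mate bases per contig), `labels` (read-contig
#'   incidence), `lib_stats`, and acceptance counters.
#' @export
map_synthetic_pairs <- function(reads, idx, spectrum, preset = idx$preset) {
  check_geometry(idx, preset)
  res <- cpp_map_synthetic(reads$seq, spectrum$insert, idx$ptr,
                           attr(spectrum, "step"), attr(spectrum, "mate_len"),
                           preset$min_mapq, preset$min_cov)
  res$read_ids <- reads$id
  res$read_lens <- nchar(reads$seq)
  res$contig_ids <- idx$ids
  res$contig_lens <- idx$lens
  res$spectrum <- spectrum
  res
}

#' Read-length N50
#' @param lens integer vector of read lengths.
#' @return the length such that reads at least that long hold half the bases.
#' @export
n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  cs <- cumsum(as.numeric(lens))
  lens[which(cs >= cs[length(cs)] / 2)[1]]
}

#' NG50 against a genome size
#' @param lens sequence lengths.
#' @param genome_size reference size in bp.
#' @return length such that sequences at least that long cover half the
#'   genome size, or NA if total length is below half the genome size.
#' @export
ng50 <- function(lens, genome_size) {
  lens <- sort(lens, decreasing = TRUE)
  cs <- cumsum(as.numeric(lens))
  i <- which(cs >= genome_size / 2)
  if (length(i) == 0) return(NA_real_)
  lens[i[1]]
}
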