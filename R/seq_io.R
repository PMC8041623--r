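#' Sequence record sets
#'
#' A `seq_set` is the currency of all sequence I/O in ssga: parallel vectors
#' of record ids, uppercase nucleotide sequences and (optionally) per-base
#' quality strings.
#'
#' @param id character vector of record ids (non-empty, unique within a set).
#' @param seq character vector of nucleotide sequences over A,C,G,T,N.
#' @param qual optional character vector of quality strings, same lengths as
#'   `seq`, or `NULL`.
#' @return an object of class `seq_set`.
#' @export
seq_set <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty record id")
  if (!is.null(qual)) {
    qual <- as.character(qual)
    if (length(qual) != length(seq)) stop("qual and seq lengths differ")
    bad <- which(nchar(qual) != nchar(seq))
    if (length(bad)) {
      stop("quality length differs from sequence length for record '",
           id[bad[1]], "'")
    }
  }
  structure(list(id = id, seq = seq, qual = qual), class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$id)

#' @export
`[.seq_set` <- function(x, i) {
  seq_set(x$id[i], x$seq[i], if (!is.null(x$qual)) x$qual[i])
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set with", length(x), "records,",
      sum(nchar(x$seq)), "bases",
      if (!is.null(x$qual)) "(with qualities)" else "", "\n")
  invisible(x)
}

#' Sequence lengths of a seq_set
#' @param x a `seq_set`.
#' @return integer vector of sequence lengths.
#' @export
seq_lengths <- function(x) nchar(x$seq)

#' Reverse complement
#' @param seq character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) cpp_revcomp(seq)

#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ file into a [seq_set]. With `format = "auto"` the
#' format is detected from the first byte (`>` vs `@`). Multi-line FASTA
#' records are concatenated and lowercase bases mapped to uppercase.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"fastq"`, `"auto"`.
#' @return a [seq_set]; FASTQ qualities are retained.
#' @export
parse_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(seq_set(character(), character()))
  if (format == "auto") {
    first <- substr(lines[1], 1, 1)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot detect format from first byte: ", path))
  }
  if (format == "fasta") {
    hdr <- grepl("^>", lines)
    if (!hdr[1]) stop("malformed FASTA: line 1 is not a header")
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    if (any(!nzchar(ids))) {
      stop("malformed FASTA: empty header at line ",
           which(hdr)[!nzchar(ids)][1])
    }
    grp <- cumsum(hdr)
    body <- !hdr & nzchar(lines)
    seqs <- vapply(split(lines[body], factor(grp[body], levels = seq_along(ids))),
                   paste0, character(1), collapse = "")
    return(seq_set(ids, seqs))
  }
  # fastq: strict 4-line records
  n <- length(lines)
  if (n %% 4 != 0) stop("malformed FASTQ: ", n, " lines is not a multiple of 4")
  i1 <- seq(1, n, by = 4)
  if (any(substr(lines[i1], 1, 1) != "@")) {
    stop("malformed FASTQ: missing '@' at line ",
         i1[substr(lines[i1], 1, 1) != "@"][1])
  }
  ids <- sub("\\s.*$", "", substring(lines[i1], 2))
  if (any(!nzchar(ids))) {
    stop("malformed FASTQ: empty header at line ", i1[!nzchar(ids)][1])
  }
  seqs <- lines[i1 + 1]
  quals <- lines[i1 + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         i1[bad[1]] + 1)
  }
  seq_set(ids, seqs, quals)
}

#' Write sequences to FASTA or FASTQ
#'
#' Writes a [seq_set] to disk. When qualities are present the output is
#' FASTQ (never wrapped); otherwise FASTA, wrapped at `wrap` columns
#' (`wrap = 0` disables wrapping). `parse_sequences(write_sequences(x))`
#' is the identity on (id, seq, qual).
#'
#' @param x a [seq_set].
#' @param path output file path.
#' @param wrap line width for FASTA output; 0 = single line per record.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, wrap = 0L) {
  stopifnot(inherits(x, "seq_set"), wrap >= 0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(x) == 0) return(invisible(path))
  if (!is.null(x$qual)) {
    out <- as.vector(rbind(paste0("@", x$id), x$seq, "+", x$qual))
  } else if (wrap == 0) {
    out <- as.vector(rbind(paste0(">", x$id), x$seq))
  } else {
    pieces <- lapply(seq_along(x$id), function(i) {
      s <- x$seq[i]
      starts <- seq(1, max(nchar(s), 1), by = wrap)
      c(paste0(">", x$id[i]), substring(s, starts, starts + wrap - 1))
    })
    out <- unlist(pieces)
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Write pseudo-alignments as SAM
#'
#' Emits a minimal SAM file (header `@HD`/`@SQ`, columns 1-11, no optional
#' tags). Internal 0-based positions are converted to SAM's 1-based `POS`
#' here and nowhere else. Strand is encoded in FLAG bit 0x10, unmapped mates
#' as FLAG 0x4 with `POS` 0; paired records additionally set 0x1 and
#' 0x40/0x80.
#'
#' @param alns data.frame with columns `qname`, `target` (target id, NA when
#'   unmapped), `pos` (0-based), `strand` (`"+"`/`"-"`), `mapq`, and
#'   optionally `seq`, `paired` (logical), `first` (logical).
#' @param path output file path.
#' @param targets data.frame with columns `id`, `length` describing every
#'   alignment target (or a [seq_set]).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alns, path, targets) {
  if (inherits(targets, "seq_set")) {
    targets <- data.frame(id = targets$id, length = seq_lengths(targets))
  }
  mapped <- !is.na(alns$target)
  if (any(!alns$target[mapped] %in% targets$id)) {
    stop("alignment references unknown target: ",
         setdiff(alns$target[mapped], targets$id)[1])
  }
  flag <- ifelse(mapped, 0L, 4L) +
    ifelse(mapped & alns$strand == "-", 16L, 0L)
  if (!is.null(alns$paired)) {
    flag <- flag + ifelse(alns$paired, 1L, 0L) +
      ifelse(alns$paired & isTRUE_vec(alns$first), 64L, 0L) +
      ifelse(alns$paired & !isTRUE_vec(alns$first), 128L, 0L)
  }
  seqcol <- if (!is.null(alns$seq)) alns$seq else rep("*", nrow(alns))
  cigar <- ifelse(mapped & seqcol != "*", paste0(nchar(seqcol), "M"),
                  ifelse(mapped, "*", "*"))
  body <- paste(alns$qname, flag,
                ifelse(mapped, alns$target, "*"),
                ifelse(mapped, alns$pos + 1L, 0L),
                ifelse(mapped, alns$mapq, 0L),
                cigar, "*", 0L, 0L, seqcol, "*", sep = "\t")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", targets$id, "\tLN:", targets$length))
  writeLines(c(hdr, body), path)
  invisible(path)
}

isTRUE_vec <- function(x) if (is.null(x)) rep(FALSE, 0) else x %in% TRUE
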