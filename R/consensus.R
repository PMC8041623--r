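#' Consensus parameters
#' @param n_reads long reads used per mate edge (default 20).
#' @param window consensus window size in bp (default 500).
#' @param min_chunk_identity chunks below this identity are dropped from
#'   their window (default 0.65).
#' @param anchor_len contig-end anchor length for boundary placement (bp).
#' @param min_anchor_identity minimum anchor alignment identity (default 0.8).
#' @param flank read flank kept around the junction span (bp).
#' @param poa_match,poa_mismatch,poa_gap partial-order-alignment scores.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(n_reads = 20L, window = 500L,
                             min_chunk_identity = 0.65, anchor_len = 2000L,
                             min_anchor_identity = 0.80, flank = 500L,
                             poa_match = 2L, poa_mismatch = -2L,
                             poa_gap = -2L) {
  stopifnot(n_reads >= 1, window >= 100)
  structure(list(n_reads = n_reads, window = window,
                 min_chunk_identity = min_chunk_identity,
                 anchor_len = anchor_len,
                 min_anchor_identity = min_anchor_identity, flank = flank,
                 poa_match = poa_match, poa_mismatch = poa_mismatch,
                 poa_gap = poa_gap),
            class = "consensus_params")
}

#' Select the best spanning reads for a mate edge
#'
#' Reads are ranked by the number of synthetic mate pairs they contributed
#' to the edge (descending; ties by read index), and the top `n` returned;
#' the first is the consensus template.
#'
#' @param g an [build_ssg] object.
#' @param e mate-edge id.
#' @param n number of reads (default 20).
#' @return data.frame (read, npairs, g_lo, g_hi, m1v), best first.
#' @export
select_spanning_reads <- function(g, e, n = 20L) {
  mr <- g$mate_reads[[e]]
  if (is.null(mr) || nrow(mr) == 0) {
    stop("mate edge ", e, " has no labeled reads; corrupt graph")
  }
  mr <- mr[order(-mr$npairs, mr$read), , drop = FALSE]
  utils::head(mr, n)
}

#' Build the per-edge long-read sequence store
#'
#' Lines are ordered by decreasing length, which imposes a global order on
#' the matched mate edges; for each edge the selected reads' junction
#' substrings (the span between the mates' junction coordinates, plus
#' `anchor_len + flank` on either side) are extracted once per (edge, read),
#' oriented to the line direction of the edge traversal.
#'
#' @param lines lines from [validate_backbone] (ordered by length).
#' @param g the [build_ssg] object.
#' @param reads long-read [seq_set] (same order as used for mapping).
#' @param params a [consensus_params].
#' @return named list (by mate-edge id) of data.frames with `read`,
#'   `npairs`, `seq` (oriented substring), in global mate-edge order.
#' @export
build_read_db <- function(lines, g, reads, params = consensus_params()) {
  pad <- params$anchor_len + params$flank
  db <- list()
  for (ln in lines) {
    if (length(ln$mate_edges) == 0) next
    for (j in seq_along(ln$mate_edges)) {
      e <- ln$mate_edges[j]
      # traversal direction: line exits contig j at this vertex
      exit_v <- line_exit_vertex(g, ln, j)
      sel <- select_spanning_reads(g, e, params$n_reads)
      rl <- nchar(reads$seq[sel$read])
      lo <- pmax(0L, pmin(sel$g_lo, sel$g_hi) - pad)
      hi <- pmin(rl, pmax(sel$g_lo, sel$g_hi) + pad)
      seqs <- substring(reads$seq[sel$read], lo + 1L, hi)
      # a read whose mate1 vertex equals the exit vertex runs line-forward
      fwd <- sel$m1v == exit_v
      seqs[!fwd] <- revcomp(seqs[!fwd])
      if (any(is.na(reads$id[sel$read]))) {
        stop("read ids missing from source: edge ", e)
      }
      db[[as.character(e)]] <- data.frame(read = sel$read,
                                          npairs = sel$npairs,
                                          seq = seqs,
                                          stringsAsFactors = FALSE)
    }
  }
  db
}

# exit vertex of contig j along line ln (the vertex the j-th mate edge leaves)
line_exit_vertex <- function(g, ln, j) {
  ci <- ln$contigs[j]
  if (ln$orient[j] > 0) v_head(ci) else v_tail(ci)
}

#' Pairwise edit alignment
#'
#' Optimal unit-cost edit distance with alignment path, by banded dynamic
#' programming (band auto-widened to at least the length difference, and to
#' `band_frac` of the longer sequence by default).
#'
#' @param query,target nucleotide strings.
#' @param max_dist optional distance bound; NULL aligns with the default
#'   band and never rejects.
#' @param band_frac default band width as a fraction of the longer length
#'   (0.15 comfortably exceeds the diagonal drift of two 5%-error reads).
#' @return list with `dist`, `ops` (per-column string over =,X,I,D),
#'   `identity` (matches / columns), or NULL when `max_dist` is exceeded.
#' @export
edit_align <- function(query, target, max_dist = NULL, band_frac = 0.15) {
  band <- if (!is.null(max_dist)) as.integer(max_dist) else
    max(32L, as.integer(ceiling(band_frac * max(nchar(query),
                                                nchar(target)))))
  r <- cpp_edit_align(query, target, band)
  if (is.na(r$dist[1])) return(NULL)
  if (!is.null(max_dist) && r$dist > max_dist) return(NULL)
  r
}

#' Windowed partial-order-alignment consensus
#'
#' The template (best spanning read) is partitioned into non-overlapping
#' windows; every other read is globally aligned to the template, its
#' alignment cut at window boundaries, and chunks with identity below
#' `min_chunk_identity` dropped. Each window's surviving chunks (template
#' chunk first) are fed to a partial-order alignment whose heaviest path is
#' the window consensus; windows with no surviving chunk pass the template
#' through unchanged. The consensus is the concatenation of window consensi.
#'
#' @param template template sequence (best spanning read substring).
#' @param others character vector of other spanning-read substrings, already
#'   oriented like the template.
#' @param params a [consensus_params].
#' @return consensus string with attribute `depth` (per-window surviving
#'   chunk count, template included).
#' @export
window_consensus <- function(template, others, params = consensus_params()) {
  tl <- nchar(template)
  w <- params$window
  nw <- max(1L, as.integer(ceiling(tl / w)))
  chunks <- vector("list", nw)
  for (s in others) {
    al <- edit_align(s, template)
    if (is.null(al)) next
    cw <- cpp_align_windows(al$ops, w, tl)
    keep <- cw$identity >= params$min_chunk_identity & cw$qend > cw$qstart
    for (wi in which(keep)) {
      chunks[[cw$win[wi]]] <- c(chunks[[cw$win[wi]]],
                                substring(s, cw$qstart[wi] + 1L, cw$qend[wi]))
    }
  }
  out <- character(nw)
  depth <- integer(nw)
  for (wi in seq_len(nw)) {
    tpl_chunk <- substring(template, (wi - 1L) * w + 1L, min(wi * w, tl))
    cs <- chunks[[wi]]
    depth[wi] <- 1L + length(cs)
    out[wi] <- if (length(cs) == 0) tpl_chunk else
      cpp_poa_consensus(c(tpl_chunk, cs), params$poa_match,
                        params$poa_mismatch, params$poa_gap)
  }
  structure(paste0(out, collapse = ""), depth = depth)
}

#' Fill backbone gaps with mate-edge consensus sequences
#'
#' For every matched mate edge a consensus is built from its spanning reads
#' ([window_consensus]); the flanking contig ends (up to `anchor_len` bp,
#' line-oriented) are aligned into the consensus to fix the boundaries, and
#' the line sequence is spliced as left contig + consensus interior + right
#' contig. Overlapping anchors (negative gap) merge the contigs at the
#' implied overlap. A contig end failing to align at
#' `min_anchor_identity` leaves the edge as a gap of `l(e)` Ns, flagged in
#' the report. Contig bases are never rewritten.
#'
#' @param lines validated lines, ordered by decreasing length.
#' @param db read store from [build_read_db].
#' @param g the [build_ssg] object.
#' @param contigs corrected contig [seq_set] (row order as in `g`).
#' @param params a [consensus_params].
#' @return list with `sequences` (named character vector of line sequences),
#'   `report` (per-edge data.frame: line, edge, l, sigma, realized, n_reads,
#'   status) and `fills` (per-edge records used by the polishers).
#' @export
fill_gaps <- function(lines, db, g, contigs, params = consensus_params()) {
  seqs <- character(length(lines))
  report <- list()
  fills <- list()
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    cseq <- oriented_contig(contigs, ln$contigs[1], ln$orient[1])
    if (length(ln$mate_edges) > 0) {
      for (j in seq_along(ln$mate_edges)) {
        e <- ln$mate_edges[j]
        entry <- db[[as.character(e)]]
        nxt <- oriented_contig(contigs, ln$contigs[j + 1L],
                               ln$orient[j + 1L])
        status <- "filled"
        realized <- NA_real_
        if (is.null(entry)) {
          status <- "no_reads"
        } else {
          cons <- window_consensus(entry$seq[1],
                                   entry$seq[-1][nzchar(entry$seq[-1])],
                                   params)
          aL <- substring(cseq, max(1L, nchar(cseq) - params$anchor_len + 1L))
          aR <- substring(nxt, 1L, params$anchor_len)
          iaL <- cpp_infix_align(aL, cons)
          iaR <- cpp_infix_align(aR, cons)
          if (iaL$identity < params$min_anchor_identity ||
              iaR$identity < params$min_anchor_identity) {
            status <- "anchor_fail"
          } else {
            realized <- iaR$tstart - iaL$tend
            fills[[length(fills) + 1]] <- list(
              line = li, edge = e, cons = as.character(cons),
              depth = attr(cons, "depth"),
              used_start = iaL$tend, used_end = iaR$tstart,
              fill_start = nchar(cseq), n_reads = nrow(entry))
            if (realized >= 0) {
              cseq <- paste0(cseq,
                             substring(cons, iaL$tend + 1L, iaR$tstart), nxt)
            } else {
              cseq <- paste0(cseq, substring(nxt, -realized + 1L))
            }
          }
        }
        if (status != "filled") {
          gap_n <- max(round(g$mate$l[e]), 1)
          cseq <- paste0(cseq, strrep("N", gap_n), nxt)
        }
        report[[length(report) + 1]] <- data.frame(
          line = li, edge = e, l = g$mate$l[e], sigma = g$mate$sigma[e],
          realized = realized,
          n_reads = if (is.null(entry)) 0L else nrow(entry), status = status)
      }
    }
    seqs[li] <- cseq
  }
  names(seqs) <- sprintf("L%d", seq_along(lines))
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(line = integer(), edge = integer(), l = numeric(),
               sigma = numeric(), realized = numeric(), n_reads = integer(),
               status = character())
  list(sequences = seqs, report = report, fills = fills)
}

oriented_contig <- function(contigs, i, orient) {
  s <- contigs$seq[i]
  if (orient > 0) s else revcomp(s)
}
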