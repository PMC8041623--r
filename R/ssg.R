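#' Mate-edge length from one accepted synthetic pair
#'
#' The mate edge induced by a pair with insert x is shortened by the overlap
#' each contig has with the fragment: `l(e) = x - (l_i - pos_f) - (l_j -
#' pos_r)`, with positions in the orientation-normalized frame (distance
#' from the contig end the mate points away from to the mate's outer
#' boundary). Negative lengths mean the contigs overlap.
#'
#' @param insert library insert size (bp).
#' @param len_i,len_j contig lengths.
#' @param pos_f,pos_r normalized mate positions.
#' @return mate-edge length estimate in bp.
#' @export
mate_edge_length <- function(insert, len_i, pos_f, len_j, pos_r) {
  insert - (len_i - pos_f) - (len_j - pos_r)
}

#' Raw mate edge from a mapped pair
#'
#' Converts two pseudo-alignments of one synthetic pair (mates on two
#' different contigs) into a raw mate edge: the endpoints are the contig-end
#' vertices each mate points toward (head when mapped `+`, tail when `-`),
#' the length follows [mate_edge_length] and sigma is the library sd.
#'
#' @param aln_f,aln_r single-row alignments (as from [map_sequence]) of the
#'   forward and reverse mate; columns target, pos, strand used.
#' @param lib list with `insert` and `sigma`.
#' @param lengths named vector of contig lengths.
#' @param mate_len mate length in bp (default 250).
#' @return list with `end_f`, `end_r` (contig id + `:head`/`:tail`), `l`,
#'   `sigma`, or NULL for a same-contig pair.
#' @export
mate_edge_from_pair <- function(aln_f, aln_r, lib, lengths, mate_len = 250L) {
  if (aln_f$target == aln_r$target) return(NULL)
  norm <- function(a) {
    l <- lengths[[a$target]]
    if (a$strand == "+") {
      list(end = paste0(a$target, ":head"), pos = a$pos)
    } else {
      list(end = paste0(a$target, ":tail"), pos = l - (a$pos + mate_len))
    }
  }
  nf <- norm(aln_f); nr <- norm(aln_r)
  l <- mate_edge_length(lib$insert, lengths[[aln_f$target]], nf$pos,
                        lengths[[aln_r$target]], nr$pos)
  list(end_f = nf$end, end_r = nr$end, l = l, sigma = lib$sigma)
}

#' Bundle raw mate edges between the same vertex pair
#'
#' Inverse-variance bundling: `l = p/q`, `sigma = sqrt(1/q)` with
#' `p = sum(l_i / sigma_i^2)`, `q = sum(1 / sigma_i^2)`; the bundled weight
#' is the sum of the constituent weights.
#'
#' @param l numeric vector of raw edge lengths.
#' @param sigma matching vector of raw edge sds (> 0).
#' @param w raw edge weights (default 1 each).
#' @return list with `l`, `sigma`, `w`.
#' @export
bundle <- function(l, sigma, w = rep(1L, length(l))) {
  if (length(l) == 0) stop("cannot bundle zero edges")
  stopifnot(length(sigma) == length(l), all(sigma > 0))
  q <- sum(1 / sigma^2)
  p <- sum(l / sigma^2)
  list(l = p / q, sigma = sqrt(1 / q), w = sum(w))
}

# vertex numbering: contig i has tail 2i-1 and head 2i
v_tail <- function(i) 2L * i - 1L
v_head <- function(i) 2L * i
v_contig <- function(v) (v + 1L) %/% 2L
v_is_head <- function(v) v %% 2L == 0L
v_partner <- function(v) ifelse(v %% 2L == 0L, v - 1L, v + 1L)

#' Build the synthetic scaffolding graph
#'
#' Vertices are contig ends (two per contig), contig edges carry length,
#' mean coverage and a long-read label set; accepted inter-contig synthetic
#' pairs become raw mate edges which are bundled per vertex pair
#' (inverse-variance length, summed weight, union of long-read labels).
#' Bundled lengths are floored at minus the shorter incident contig length.
#'
#' @param contigs a [seq_set] of (corrected) contigs.
#' @param mapres result of [map_synthetic_pairs] on these contigs.
#' @param short_cov optional named per-contig mean short-read coverage; when
#'   absent, mapped synthetic-mate base coverage is used as the proxy.
#' @return object of class `ssg`.
#' @export
build_ssg <- function(contigs, mapres, short_cov = NULL) {
  nctg <- length(contigs)
  lens <- seq_lengths(contigs)
  pr <- mapres$pairs
  if (nrow(pr) > 0 && (max(pr$c1, pr$c2) > nctg)) {
    stop("pair alignments reference unknown contigs")
  }
  cov <- if (!is.null(short_cov)) {
    as.numeric(short_cov[contigs$id])
  } else {
    mapres$covbases / lens
  }
  ctg <- data.frame(id = contigs$id, len = lens, cov = cov,
                    repeat_flag = FALSE, stringsAsFactors = FALSE)
  # contig labels: reads with an accepted mate mapped within the contig
  clabels <- rep(list(integer(0)), nctg)
  if (nrow(mapres$labels) > 0) {
    sp <- split(mapres$labels$read, mapres$labels$contig)
    for (cn in names(sp)) clabels[[as.integer(cn)]] <- sort(unique(sp[[cn]]))
  }
  sp_sigma <- mapres$spectrum$sigma
  sp_insert <- mapres$spectrum$insert
  if (nrow(pr) == 0) {
    mate <- data.frame(u = integer(), v = integer(), l = numeric(),
                       sigma = numeric(), w = integer())
    return(structure(list(contigs = ctg, contig_labels = clabels,
                          mate = mate, mate_reads = list(),
                          reads = mapres$read_ids,
                          read_lens = mapres$read_lens, spectrum = mapres$spectrum,
                          n_accepted_inter = 0L),
                     class = "ssg"))
  }
  dt <- data.table::as.data.table(pr)
  dt[, `:=`(sigma = sp_sigma[lib], insert = sp_insert[lib])]
  dt[, lraw := insert - (lens[c1] - pos1) - (lens[c2] - pos2)]
  dt[, `:=`(u = pmin(v1, v2), v = pmax(v1, v2))]
  med <- dt[, .(l = sum(lraw / sigma^2) / sum(1 / sigma^2),
                sigma = sqrt(1 / sum(1 / sigma^2)),
                w = .N), by = .(u, v)]
  data.table::setorder(med, u, v)
  # floor strongly negative bundled lengths
  floor_l <- -pmin(lens[v_contig(med$u)], lens[v_contig(med$v)])
  med[, l := pmax(l, floor_l)]
  med[, id := .I]
  # per-edge per-read support: pair count and junction coordinates from the
  # smallest-insert (most precise) pair of that read on that edge
  data.table::setorder(dt, u, v, read, lib, offset)
  per_read <- dt[, .(npairs = .N, g_lo = g1[1], g_hi = g2[1],
                     m1v = v1[1], min_insert = insert[1]),
                 by = .(u, v, read)]
  key <- paste(per_read$u, per_read$v)
  mkey <- paste(med$u, med$v)
  idx_map <- match(key, mkey)
  mate_reads <- vector("list", nrow(med))
  spl <- split(seq_len(nrow(per_read)), idx_map)
  for (nm in names(spl)) {
    rows <- per_read[spl[[nm]]]
    data.table::setorder(rows, -npairs, read)
    mate_reads[[as.integer(nm)]] <- as.data.frame(rows[, .(read, npairs,
                                                           g_lo, g_hi, m1v)])
  }
  mate <- as.data.frame(med[, .(id, u, v, l, sigma, w)])
  structure(list(contigs = ctg, contig_labels = clabels, mate = mate,
                 mate_reads = mate_reads, reads = mapres$read_ids,
                 read_lens = mapres$read_lens, spectrum = mapres$spectrum,
                 n_accepted_inter = nrow(pr)),
            class = "ssg")
}

#' @export
print.ssg <- function(x, ...) {
  cat("ssg:", nrow(x$contigs), "contigs,", nrow(x$mate), "bundled mate edges",
      sprintf("(total weight %d)", sum(x$mate$w)),
      if (any(x$contigs$repeat_flag)) sprintf(", %d repeat-masked",
                                              sum(x$contigs$repeat_flag))
      else "", "\n")
  invisible(x)
}

#' Mate-edge label sets
#'
#' @param g an [build_ssg] object.
#' @param e mate-edge id.
#' @return sorted integer vector of supporting long-read indices.
#' @export
edge_labels <- function(g, e) {
  mr <- g$mate_reads[[e]]
  if (is.null(mr)) integer(0) else sort(mr$read)
}

#' Dump an SSG as TSV tables
#'
#' Writes a three-section TSV (contig table; mate-edge table with l, sigma,
#' w, label count) for inspection and fixtures.
#' @param g an `ssg`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_ssg <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#contigs\tid\tlen\tcov\trepeat", con)
  writeLines(sprintf("C\t%s\t%d\t%.2f\t%d", g$contigs$id, g$contigs$len,
                     g$contigs$cov, as.integer(g$contigs$repeat_flag)), con)
  writeLines("#mate_edges\tu\tv\tl\tsigma\tw\tnreads", con)
  if (nrow(g$mate)) {
    nr <- vapply(g$mate_reads, nrow, integer(1))
    writeLines(sprintf("M\t%d\t%d\t%.1f\t%.2f\t%d\t%d", g$mate$u, g$mate$v,
                       g$mate$l, g$mate$sigma, g$mate$w, nr), con)
  }
  invisible(path)
}
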