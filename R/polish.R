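#' Polishing parameters
#' @param max_iterations DFS extension cap per mate edge (default 5e6).
#' @param id_floor,id_ceiling expected-identity endpoints over depth 1..20.
#' @param min_contig_cov minimum fraction of the contig edge the alignment
#'   must cover (default 0.75).
#' @param polish_w,polish_k minimizer geometry of the alignment polisher.
#' @param max_minimizer_freq consensus minimizers above this frequency are
#'   excluded from the polish index (default 1000).
#' @param min_extra_bp unused contigs longer than this are appended to the
#'   final assembly (default 5000).
#' @return list of class `polish_params`.
#' @export
polish_params <- function(max_iterations = 5e6, id_floor = 0.80,
                          id_ceiling = 0.99, min_contig_cov = 0.75,
                          polish_w = 5L, polish_k = 17L,
                          max_minimizer_freq = 1000L, min_extra_bp = 5000L) {
  stopifnot(id_floor < id_ceiling)
  structure(list(max_iterations = max_iterations, id_floor = id_floor,
                 id_ceiling = id_ceiling, min_contig_cov = min_contig_cov,
                 polish_w = polish_w, polish_k = polish_k,
                 max_minimizer_freq = max_minimizer_freq,
                 min_extra_bp = min_extra_bp),
            class = "polish_params")
}

#' Expected consensus identity as a function of long-read depth
#'
#' Linear interpolation between 80% identity at depth 1 and 99% at depth 20,
#' clamped outside that range: a consensus built from few reads is held to a
#' laxer standard than a deep one.
#'
#' @param depth mean long-read depth of the consensus region (>= 0).
#' @param params a [polish_params].
#' @return expected minimum identity in [id_floor, id_ceiling].
#' @export
expected_identity <- function(depth, params = polish_params()) {
  d <- pmin(pmax(depth, 1), 20)
  params$id_floor + (d - 1) * (params$id_ceiling - params$id_floor) / 19
}

# splice a replacement into a line sequence, shifting later fill records
splice_line <- function(seqs, fills, fi, rep_start, rep_end, replacement) {
  f <- fills[[fi]]
  li <- f$line
  s <- seqs[li]
  seqs[li] <- paste0(substring(s, 1L, rep_start),
                     replacement,
                     substring(s, rep_end + 1L))
  shift <- nchar(replacement) - (rep_end - rep_start)
  if (shift != 0) {
    for (k in seq_along(fills)) {
      if (k == fi || fills[[k]]$line != li) next
      if (fills[[k]]$fill_start >= rep_end) {
        fills[[k]]$fill_start <- fills[[k]]$fill_start + shift
      }
    }
    fills[[fi]]$used_end <- fills[[fi]]$used_start +
      (fills[[fi]]$used_end - fills[[fi]]$used_start) + shift
  }
  list(seqs = seqs, fills = fills)
}

# try to splice one contig into the filled interval of one edge record
try_splice_contig <- function(seqs, fills, fi, contig_seq, params) {
  f <- fills[[fi]]
  span <- f$used_end - f$used_start
  if (span <= 0) return(NULL)
  region_start <- f$fill_start
  region_end <- f$fill_start + span
  region <- substring(seqs[f$line], region_start + 1L, region_end)
  if (nchar(region) < 50 || nchar(contig_seq) > 4 * nchar(region)) {
    return(NULL)
  }
  ia <- cpp_infix_align(contig_seq, region)
  depth <- mean(f$depth)
  if (ia$identity < expected_identity(depth, params)) return(NULL)
  aligned_span <- ia$tend - ia$tstart
  if (aligned_span < params$min_contig_cov * nchar(contig_seq)) return(NULL)
  res <- splice_line(seqs, fills, fi,
                     region_start + ia$tstart, region_start + ia$tend,
                     contig_seq)
  res$identity <- ia$identity
  res
}

#' Graph polisher: splice leftover contigs via long-read-coherent paths
#'
#' For each filled mate edge, long-read-coherent paths are searched as in
#' transitive reduction but with the backbone contigs masked, so the paths
#' traverse leftover (repeat / short) contigs; each traversed contig is
#' aligned (in path orientation) to the filled consensus interval and
#' spliced in when its identity reaches [expected_identity] at the region's
#' read depth and the alignment covers at least `min_contig_cov` of the
#' contig. The DFS is capped at `max_iterations` extensions per edge.
#'
#' @param seqs line sequences from [fill_gaps].
#' @param fills fill records from [fill_gaps].
#' @param g the reduced [build_ssg] object.
#' @param lines the validated lines.
#' @param contigs corrected contig [seq_set].
#' @param params a [polish_params].
#' @param rparams a [reduction_params].
#' @return list with `sequences`, `fills`, `used` (logical per contig),
#'   `report`.
#' @export
graph_polish <- function(seqs, fills, g, lines, contigs,
                         params = polish_params(),
                         rparams = reduction_params()) {
  n <- nrow(g$contigs)
  backbone <- rep(FALSE, n)
  for (ln in lines) if (length(ln$contigs) > 1) backbone[ln$contigs] <- TRUE
  used <- rep(FALSE, n)
  report <- list()
  if (length(fills) == 0 || all(backbone)) {
    return(list(sequences = seqs, fills = fills, used = used,
                report = data.frame()))
  }
  active <- !g$mate$removed
  adj <- mate_adjacency(g, active)
  bc <- ssg_biconnected(g)
  for (fi in seq_along(fills)) {
    e <- fills[[fi]]$edge
    act <- active; act[e] <- FALSE
    res <- coherent_paths(g, e, rparams, adj = adj, mate_comp = bc$mate_comp,
                          active = act,
                          iter_budget = params$max_iterations,
                          masked_contigs = backbone)
    capped <- !is.null(res) && length(res) == 0
    if (is.null(res) || length(res) == 0 || length(res$contig_ids) == 0) {
      if (capped) {
        report[[length(report) + 1]] <- data.frame(
          edge = e, contig = NA_character_, identity = NA_real_,
          action = "iteration_cap")
      }
      next
    }
    # orientation along the path from the edge's u endpoint
    orient <- path_contig_orientations(g, e, res)
    for (t in seq_along(res$contig_ids)) {
      ci <- res$contig_ids[t]
      cs <- oriented_contig(contigs, ci, orient[t])
      out <- try_splice_contig(seqs, fills, fi, cs, params)
      if (!is.null(out)) {
        seqs <- out$seqs; fills <- out$fills
        used[ci] <- TRUE
        report[[length(report) + 1]] <- data.frame(
          edge = e, contig = g$contigs$id[ci], identity = out$identity,
          action = "spliced")
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else data.frame()
  list(sequences = seqs, fills = fills, used = used, report = report)
}

# orientation of each traversed contig along a coherent path starting at u(e):
# the path enters contig at some end; forward when entered at the tail.
path_contig_orientations <- function(g, e, res) {
  cur <- g$mate$u[e]
  orient <- integer(length(res$contig_ids))
  for (t in seq_along(res$mate_edges)) {
    me <- res$mate_edges[t]
    nxt <- if (g$mate$u[me] == cur) g$mate$v[me] else g$mate$u[me]
    if (t <= length(res$contig_ids)) {
      orient[t] <- if (v_is_head(nxt)) -1L else 1L
      cur <- v_partner(nxt)
    }
  }
  orient
}

#' Alignment polisher: splice leftover contigs via minimizer hits
#'
#' Consensus (filled) intervals are indexed with (5,17)-minimizers
#' (minimizers above `max_minimizer_freq` occurrences excluded); every
#' unused non-backbone contig is scanned against the index, hits are
#' co-linear chains, and a greedy layout (hits sorted by minimizer matches,
#' added only when non-overlapping) selects where each consensus is
#' polished, exactly as in the graph polisher.
#'
#' @inheritParams graph_polish
#' @param used logical per contig (already consumed by the graph polisher).
#' @return list with `sequences`, `fills`, `used`, `report`.
#' @export
alignment_polish <- function(seqs, fills, g, lines, contigs, used,
                             params = polish_params()) {
  n <- nrow(g$contigs)
  backbone <- rep(FALSE, n)
  for (ln in lines) if (length(ln$contigs) > 1) backbone[ln$contigs] <- TRUE
  cand <- which(!backbone & !used)
  report <- list()
  if (length(cand) == 0 || length(fills) == 0) {
    return(list(sequences = seqs, fills = fills, used = used,
                report = data.frame()))
  }
  # index the filled consensus intervals
  cons_seqs <- vapply(fills, function(f) {
    span <- f$used_end - f$used_start
    if (span <= 0) return("")
    substring(seqs[f$line], f$fill_start + 1L, f$fill_start + span)
  }, character(1))
  ok <- nzchar(cons_seqs) & nchar(cons_seqs) >= params$polish_k
  if (!any(ok)) {
    return(list(sequences = seqs, fills = fills, used = used,
                report = data.frame()))
  }
  pol_preset <- structure(list(name = "polish", w = params$polish_w,
                               k = params$polish_k, hpc = FALSE,
                               min_mapq = 0L, min_cov = 0,
                               max_occ = params$max_minimizer_freq),
                          class = "preset")
  cidx <- build_index(seq_set(sprintf("fill%d", which(ok)), cons_seqs[ok]),
                      pol_preset)
  hits <- cpp_map_all_chains(contigs$seq[cand], cidx$ptr)
  if (nrow(hits) == 0) {
    return(list(sequences = seqs, fills = fills, used = used,
                report = data.frame()))
  }
  hits$fill_idx <- which(ok)[hits$target]
  hits$contig_row <- cand[hits$query]
  hits <- hits[order(-hits$score, hits$contig_row), , drop = FALSE]
  laid <- list()  # per fill: matrix of occupied intervals
  for (h in seq_len(nrow(hits))) {
    fi <- hits$fill_idx[h]
    ci <- hits$contig_row[h]
    if (used[ci]) next
    clen <- g$contigs$len[ci]
    iv <- c(hits$pos[h], hits$pos[h] + clen)
    key <- as.character(fi)
    prev <- laid[[key]]
    overlaps <- !is.null(prev) &&
      any(prev[, 1] < iv[2] & prev[, 2] > iv[1])
    if (overlaps) next
    laid[[key]] <- rbind(prev, iv)
    cs <- oriented_contig(contigs, ci, if (hits$strand[h] == 0) 1L else -1L)
    out <- try_splice_contig(seqs, fills, fi, cs, params)
    if (!is.null(out)) {
      seqs <- out$seqs; fills <- out$fills
      used[ci] <- TRUE
      report[[length(report) + 1]] <- data.frame(
        edge = fills[[fi]]$edge, contig = g$contigs$id[ci],
        identity = out$identity, action = "spliced_aln")
    }
  }
  report <- if (length(report)) do.call(rbind, report) else data.frame()
  list(sequences = seqs, fills = fills, used = used, report = report)
}

#' Emit the final assembly
#'
#' One record per line (ids `ssga-L1`, `ssga-L2`, ... by decreasing length),
#' plus every contig that is neither part of a multi-contig line nor
#' consumed by a polisher, when longer than `min_extra_bp`.
#'
#' @param seqs polished line sequences.
#' @param lines the validated lines.
#' @param g the [build_ssg] object.
#' @param contigs corrected contig [seq_set].
#' @param used logical per contig (consumed by polishing).
#' @param params a [polish_params].
#' @return a [seq_set] of the final assembly.
#' @export
emit_assembly <- function(seqs, lines, g, contigs, used,
                          params = polish_params()) {
  multi <- vapply(lines, function(l) length(l$contigs) > 1, logical(1))
  line_seqs <- seqs[multi]
  ord <- order(-nchar(line_seqs))
  out_id <- sprintf("ssga-L%d", seq_along(line_seqs))
  out_seq <- line_seqs[ord]
  line_of <- which(multi)[ord]
  # singleton-line contigs: extras if unused and long enough
  singles <- unlist(lapply(lines[!multi], `[[`, "contigs"))
  extra <- singles[!used[singles] & g$contigs$len[singles] > params$min_extra_bp]
  if (length(extra)) {
    out_id <- c(out_id, g$contigs$id[extra])
    out_seq <- c(out_seq, contigs$seq[extra])
    line_of <- c(line_of, rep(NA_integer_, length(extra)))
  }
  out <- seq_set(out_id, out_seq)
  # which line each record came from (NA for leftover contigs)
  attr(out, "line_index") <- line_of
  out
}
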