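#' Maximum-weight matching cover of the reduced SSG
#'
#' Mate edges touching repeat contigs, already reduced, or with weight below
#' `min_weight` are masked; over the remaining edges a maximum-weight
#' matching (each contig end matched at most once) is computed. Connected
#' components of the eligible mate-edge graph up to `exact_max_vertices`
#' vertices are solved exactly by subset dynamic programming; larger
#' components fall back to the greedy heuristic (take edges in decreasing
#' weight while both ends are free), which carries the classical worst-case
#' performance ratio.
#'
#' @param g a reduced [build_ssg] object.
#' @param min_weight minimum bundled weight for an eligible edge (default 5).
#' @param exact_max_vertices exact-solver component size cap.
#' @param greedy_only force the greedy heuristic everywhere.
#' @return list of class `matching_result`: `edges` (matched mate-edge ids),
#'   `w_matched`, `w_total` (total eligible weight), `ratio`, `exact`
#'   (logical: all components solved exactly).
#' @export
matching_cover <- function(g, min_weight = 5L, exact_max_vertices = 22L,
                           greedy_only = FALSE) {
  rep_v <- g$contigs$repeat_flag
  removed <- if (!is.null(g$mate$removed)) g$mate$removed else
    rep(FALSE, nrow(g$mate))
  elig <- !removed & g$mate$w >= min_weight &
    !rep_v[v_contig(g$mate$u)] & !rep_v[v_contig(g$mate$v)]
  rows <- which(elig)
  if (length(rows) == 0) {
    return(structure(list(edges = integer(0), w_matched = 0,
                          w_total = 0, ratio = NA_real_, exact = TRUE),
                     class = "matching_result"))
  }
  verts <- sort(unique(c(g$mate$u[rows], g$mate$v[rows])))
  vid <- match(c(g$mate$u[rows], g$mate$v[rows]), verts)
  uu <- vid[seq_along(rows)]
  vv <- vid[seq_along(rows) + length(rows)]
  ig <- igraph::graph_from_edgelist(cbind(uu, vv), directed = FALSE)
  comp <- igraph::components(ig)$membership
  matched <- integer(0)
  all_exact <- TRUE
  for (ci in sort(unique(comp[uu]))) {
    cvs <- which(comp == ci)
    er <- which(uu %in% cvs)
    if (length(er) == 0) next
    if (!greedy_only && length(cvs) <= exact_max_vertices) {
      lu <- match(uu[er], cvs) - 1L
      lv <- match(vv[er], cvs) - 1L
      sol <- cpp_mwm_exact(length(cvs), lu, lv, as.numeric(g$mate$w[rows[er]]))
      matched <- c(matched, rows[er][sol$edges])
    } else {
      all_exact <- FALSE
      ord <- er[order(-g$mate$w[rows[er]], g$mate$id[rows[er]])]
      free <- rep(TRUE, max(c(uu[er], vv[er])))
      for (e2 in ord) {
        if (free[uu[e2]] && free[vv[e2]]) {
          matched <- c(matched, rows[e2])
          free[uu[e2]] <- FALSE
          free[vv[e2]] <- FALSE
        }
      }
    }
  }
  matched <- sort(matched)
  w_m <- sum(g$mate$w[matched])
  w_t <- sum(g$mate$w[rows])
  structure(list(edges = matched, w_matched = w_m, w_total = w_t,
                 ratio = w_m / w_t, exact = all_exact),
            class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat(sprintf("matching_cover: %d matched edges, W(S)=%s, W(G)=%s, r=%.3f%s\n",
              length(x$edges), format(x$w_matched), format(x$w_total),
              x$ratio, if (x$exact) " (exact)" else " (greedy)"))
  invisible(x)
}

#' Extract backbone lines, destroying cycles
#'
#' Contig edges are added to the matched mate edges; every vertex then has
#' degree at most two, so components are simple paths or cycles. Each cycle
#' is destroyed by removing its lowest-weight mate edge (ties by edge id).
#' Remaining components become `line`s: ordered, oriented alternating
#' sequences of contigs and mate edges, with line coordinates accumulated
#' from contig lengths and mate-edge length estimates (clamped at 1 bp for
#' coordinate monotonicity; raw estimates are kept per edge).
#'
#' @param g a reduced [build_ssg] object.
#' @param matching a [matching_cover] result.
#' @return list of lines; each line is a list with `contigs` (row indices),
#'   `orient` (+1 forward tail->head), `mate_edges` (ids between successive
#'   contigs), `gaps` (raw l estimates), `starts` (line coordinate of each
#'   contig), `length`.
#' @export
break_cycles_extract_lines <- function(g, matching) {
  n <- nrow(g$contigs)
  medges <- matching$edges
  # mate-degree per vertex is <= 1 by matching
  mate_at <- rep(NA_integer_, 2L * n)
  for (e in medges) {
    mate_at[g$mate$u[e]] <- e
    mate_at[g$mate$v[e]] <- e
  }
  # detect cycles: walk components; a component is a cycle iff every vertex
  # has mate degree 1
  visited <- rep(FALSE, n)
  drop_edges <- integer(0)
  for (start in seq_len(n)) {
    if (visited[start]) next
    # walk right from head, left from tail; if we return to start, cycle
    comp_edges <- integer(0)
    cyc <- FALSE
    ctg <- start; vtx <- v_head(start)
    visited[start] <- TRUE
    repeat {
      e <- mate_at[vtx]
      if (is.na(e)) break
      comp_edges <- c(comp_edges, e)
      nxt <- if (g$mate$u[e] == vtx) g$mate$v[e] else g$mate$u[e]
      nctg <- v_contig(nxt)
      if (nctg == start) { cyc <- TRUE; break }
      visited[nctg] <- TRUE
      vtx <- v_partner(nxt)
    }
    if (!cyc && length(comp_edges) >= 0) {
      # also walk the other direction to mark the full component
      vtx <- v_tail(start)
      repeat {
        e <- mate_at[vtx]
        if (is.na(e)) break
        nxt <- if (g$mate$u[e] == vtx) g$mate$v[e] else g$mate$u[e]
        nctg <- v_contig(nxt)
        if (visited[nctg]) break
        visited[nctg] <- TRUE
        vtx <- v_partner(nxt)
      }
    }
    if (cyc) {
      wmin <- which.min(g$mate$w[comp_edges] +
                          g$mate$id[comp_edges] / (max(g$mate$id) + 1))
      drop_edges <- c(drop_edges, comp_edges[wmin])
      mate_at[g$mate$u[comp_edges[wmin]]] <- NA_integer_
      mate_at[g$mate$v[comp_edges[wmin]]] <- NA_integer_
    }
  }
  # extract simple paths from free ends
  used <- rep(FALSE, n)
  lines <- list()
  free_vs <- which(is.na(mate_at))
  for (v0 in free_vs) {
    ctg0 <- v_contig(v0)
    if (used[ctg0]) next
    used[ctg0] <- TRUE
    # traverse away from the free end: enter the contig at v0
    orient0 <- if (v_is_head(v0)) -1L else 1L  # entering at tail = forward
    contigs <- ctg0; orient <- orient0
    mes <- integer(0); gaps <- numeric(0)
    vtx <- v_partner(v0)  # exit vertex
    repeat {
      e <- mate_at[vtx]
      if (is.na(e)) break
      nxt <- if (g$mate$u[e] == vtx) g$mate$v[e] else g$mate$u[e]
      nctg <- v_contig(nxt)
      if (used[nctg]) break
      used[nctg] <- TRUE
      mes <- c(mes, e)
      gaps <- c(gaps, g$mate$l[e])
      contigs <- c(contigs, nctg)
      orient <- c(orient, if (v_is_head(nxt)) -1L else 1L)
      vtx <- v_partner(nxt)
    }
    starts <- numeric(length(contigs))
    pos <- 0
    for (i in seq_along(contigs)) {
      starts[i] <- pos
      pos <- pos + g$contigs$len[contigs[i]]
      if (i <= length(gaps)) pos <- pos + max(gaps[i], 1)
    }
    lines[[length(lines) + 1]] <-
      list(contigs = contigs, orient = orient, mate_edges = mes,
           gaps = gaps, starts = starts, length = pos)
  }
  lines[order(-vapply(lines, `[[`, numeric(1), "length"),
              vapply(lines, function(l) l$contigs[1], integer(1)))]
}

#' Validation parameters for backbone joins
#' @param min_overlap minimum long-read overlap length O (bp, default 20 kb).
#' @param min_support split a suspicious join when fewer than this many long
#'   reads support it (default 4).
#' @return list of class `validation_params`.
#' @export
validation_params <- function(min_overlap = 20000, min_support = 4L) {
  stopifnot(min_overlap > 0, min_support >= 1)
  structure(list(min_overlap = min_overlap, min_support = min_support),
            class = "validation_params")
}

#' Validate backbone joins with long-read physical coverage
#'
#' Per line, physical fragments are created from (a) contig edges, (b) mate
#' edges whose supporting reads are at least `min_overlap` long (the read
#' span around the junction becomes the fragment), and (c) reduced mate
#' edges whose endpoints lie in the same line, whose length exceeds
#' `min_overlap`, and whose length matches the in-line path within
#' `4 max(sigma(e), sigma(pf))`. Mate-edge loci with zero fragment coverage
#' from (b)/(c) are suspicious; the line is split there iff fewer than
#' `min_support` long reads support the join.
#'
#' @param lines output of [break_cycles_extract_lines].
#' @param g the reduced [build_ssg] object.
#' @param path_db path database from [transitive_reduce].
#' @param params a [validation_params].
#' @return list with `lines` (split as needed) and `report` (data.frame
#'   line, edge, support, covered, split).
#' @export
validate_backbone <- function(lines, g, path_db,
                              params = validation_params()) {
  report <- list()
  out_lines <- list()
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    k <- length(ln$contigs)
    if (k == 1) { out_lines[[length(out_lines) + 1]] <- ln; next }
    # line coordinate of each vertex (contig ends)
    vcoord_start <- ln$starts
    vcoord_end <- ln$starts + g$contigs$len[ln$contigs]
    # mate-edge loci
    mstart <- vcoord_end[-k]
    mend <- vcoord_start[-1]
    frags <- list()
    # (b) read-span fragments over each mate edge
    support <- integer(k - 1L)
    for (j in seq_len(k - 1L)) {
      e <- ln$mate_edges[j]
      mr <- g$mate_reads[[e]]
      support[j] <- nrow(mr)
      if (is.null(g$read_lens)) next
      rl <- g$read_lens[mr$read]
      long <- which(rl >= params$min_overlap)
      for (t in long) {
        left_ext <- min(mr$g_lo[t], mr$g_hi[t])
        right_ext <- rl[t] - max(mr$g_lo[t], mr$g_hi[t])
        frags[[length(frags) + 1]] <-
          c(mstart[j] - max(left_ext, 0), mend[j] + max(right_ext, 0))
      }
    }
    # (c) reduced-edge path fragments within this line
    if (nrow(path_db) > 0) {
      vmap <- rep(NA_real_, 2L * nrow(g$contigs))
      for (i in seq_len(k)) {
        ci <- ln$contigs[i]
        if (ln$orient[i] > 0) {
          vmap[v_tail(ci)] <- vcoord_start[i]
          vmap[v_head(ci)] <- vcoord_end[i]
        } else {
          vmap[v_head(ci)] <- vcoord_start[i]
          vmap[v_tail(ci)] <- vcoord_end[i]
        }
      }
      for (r in seq_len(nrow(path_db))) {
        if (path_db$l_e[r] <= params$min_overlap) next
        cu <- vmap[path_db$u[r]]; cv <- vmap[path_db$v[r]]
        if (is.na(cu) || is.na(cv)) next
        lpf <- abs(cv - cu)
        tolr <- 4 * max(path_db$sigma_e[r], path_db$sigma_p[r])
        if (abs(path_db$l_e[r] - lpf) > tolr) next
        frags[[length(frags) + 1]] <- c(min(cu, cv), max(cu, cv))
      }
    }
    # coverage at mate loci
    covered <- logical(k - 1L)
    for (j in seq_len(k - 1L)) {
      a <- mstart[j]; b <- max(mend[j], mstart[j] + 1)
      covered[j] <- any(vapply(frags, function(f) f[1] < a && f[2] > b,
                               logical(1)))
    }
    split_at <- which(!covered & support < params$min_support)
    report[[length(report) + 1]] <- data.frame(
      line = li, edge = ln$mate_edges, support = support,
      covered = covered, split = seq_len(k - 1L) %in% split_at)
    # split the line
    cuts <- c(0L, split_at, k)
    for (s in seq_len(length(cuts) - 1L)) {
      idx <- (cuts[s] + 1L):cuts[s + 1L]
      sub <- list(contigs = ln$contigs[idx], orient = ln$orient[idx],
                  mate_edges = ln$mate_edges[idx[-length(idx)]],
                  gaps = ln$gaps[idx[-length(idx)]],
                  starts = ln$starts[idx] - ln$starts[idx[1]],
                  length = NA)
      sub$length <- sub$starts[length(idx)] +
        g$contigs$len[sub$contigs[length(idx)]] - sub$starts[1]
      out_lines[[length(out_lines) + 1]] <- sub
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(line = integer(), edge = integer(), support = integer(),
               covered = logical(), split = logical())
  out_lines <- out_lines[order(-vapply(out_lines, `[[`, numeric(1), "length"))]
  list(lines = out_lines, report = report)
}
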