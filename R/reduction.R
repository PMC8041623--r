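#' Reduction parameters
#'
#' @param tol_multiplier path-length tolerance, in units of
#'   `max(sigma(e), sigma(P))` (default 4).
#' @param max_path_vertices prune partial paths beyond this many vertices.
#' @param max_paths_long stop after this many coherent paths for long edges.
#' @param long_edge_bp threshold defining a long edge (default 100 kb).
#' @param repeat_multiplier coverage multiplier for repeat masking.
#' @param unique_fraction fraction of longest contigs used as the
#'   unique-coverage proxy.
#' @param max_iterations cap on DFS edge extensions per searched edge (used
#'   by the graph polisher).
#' @return list of class `reduction_params`.
#' @export
reduction_params <- function(tol_multiplier = 4, max_path_vertices = 80L,
                             max_paths_long = 100L, long_edge_bp = 1e5,
                             repeat_multiplier = 1.5, unique_fraction = 0.10,
                             max_iterations = 5e6) {
  p <- list(tol_multiplier = tol_multiplier,
            max_path_vertices = max_path_vertices,
            max_paths_long = max_paths_long, long_edge_bp = long_edge_bp,
            repeat_multiplier = repeat_multiplier,
            unique_fraction = unique_fraction,
            max_iterations = max_iterations)
  stopifnot(all(unlist(p) > 0))
  class(p) <- "reduction_params"
  p
}

#' Mask repeat contigs by relative coverage
#'
#' The mean coverage of unique regions is estimated from the longest
#' `unique_fraction` of contigs (by count, at least one), all likely to be
#' single-copy; contig edges with mean coverage strictly above
#' `repeat_multiplier` times that estimate are flagged as repeats. Flags are
#' never unset downstream.
#'
#' @param g an [build_ssg] object with per-contig coverage.
#' @param params a [reduction_params].
#' @return `g` with `contigs$repeat_flag` set; the unique-coverage estimate
#'   is attached as attribute `u_bar`.
#' @export
mask_repeats <- function(g, params = reduction_params()) {
  if (all(is.na(g$contigs$cov))) stop("no coverage data for repeat masking")
  n <- nrow(g$contigs)
  topn <- max(1L, floor(params$unique_fraction * n))
  ord <- order(g$contigs$len, decreasing = TRUE)
  u_bar <- mean(g$contigs$cov[ord[seq_len(topn)]])
  g$contigs$repeat_flag <- g$contigs$repeat_flag |
    (g$contigs$cov > params$repeat_multiplier * u_bar)
  attr(g, "u_bar") <- u_bar
  g
}

# igraph over contig ends: contig edges first (rows 1..n), then mate edges.
ssg_igraph <- function(g, mate_rows = seq_len(nrow(g$mate))) {
  n <- nrow(g$contigs)
  el <- rbind(cbind(v_tail(seq_len(n)), v_head(seq_len(n))),
              cbind(g$mate$u[mate_rows], g$mate$v[mate_rows]))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Biconnected components of the SSG
#'
#' Decomposes the graph (contig edges plus mate edges) into biconnected
#' components; every edge belongs to exactly one component.
#'
#' @param g an [build_ssg] object.
#' @return list with `contig_comp` and `mate_comp` (integer component id per
#'   contig edge / mate edge) and `articulation` (vertex ids).
#' @export
ssg_biconnected <- function(g) {
  ig <- ssg_igraph(g)
  bc <- igraph::biconnected_components(ig)
  n <- nrow(g$contigs)
  m <- nrow(g$mate)
  comp <- integer(n + m)
  for (ci in seq_along(bc$component_edges)) {
    comp[as.integer(bc$component_edges[[ci]])] <- ci
  }
  list(contig_comp = comp[seq_len(n)],
       mate_comp = if (m > 0) comp[n + seq_len(m)] else integer(0),
       articulation = as.integer(bc$articulation_points))
}

# label subset test: is set a (sorted int) contained in set b (sorted int)?
is_subset <- function(a, b) all(a %in% b)

# adjacency list of mate edges per vertex, children ordered by ascending
# bundled length then incident contig id (deterministic DFS order)
mate_adjacency <- function(g, active) {
  adj <- vector("list", 2L * nrow(g$contigs))
  rows <- which(active)
  ord <- rows[order(g$mate$l[rows], g$contigs$id[v_contig(g$mate$u[rows])],
                    g$mate$id[rows])]
  for (e in ord) {
    u <- g$mate$u[e]; v <- g$mate$v[e]
    adj[[u]] <- c(adj[[u]], e)
    adj[[v]] <- c(adj[[v]], e)
  }
  adj
}

#' Search long-read-coherent paths for a mate edge
#'
#' Depth-first enumeration of transitive paths between the endpoints of mate
#' edge `e` over unmasked edges of the same biconnected component. A path is
#' long-read coherent when `|l(e) - l(P)| <= tol * max(sigma(e), sigma(P))`
#' and the label set of `e` is contained in the label set of every edge of
#' the path. Partial paths are pruned past `max_path_vertices` vertices or
#' when already too long; for edges of `long_edge_bp` or more the search
#' stops after `max_paths_long` complete paths. Among coherent paths the one
#' with the most supporting-read pair hits is returned.
#'
#' @param g an [build_ssg] object (repeats masked).
#' @param e mate-edge id to reduce.
#' @param params a [reduction_params].
#' @param adj optional precomputed [mate_adjacency] (active edges).
#' @param mate_comp per-mate-edge biconnected component ids.
#' @param active logical vector of usable mate edges.
#' @param iter_budget optional cap on DFS extensions (graph polisher).
#' @param masked_contigs optional logical per contig: not traversable.
#' @return NULL or list with `mate_edges`, `contig_ids` (traversed contig
#'   rows), `l`, `sigma`, `hits`, `iterations`, `capped`.
#' @export
coherent_paths <- function(g, e, params = reduction_params(), adj = NULL,
                           mate_comp = NULL, active = NULL,
                           iter_budget = Inf, masked_contigs = NULL) {
  m <- nrow(g$mate)
  if (is.null(active)) { active <- rep(TRUE, m); active[e] <- FALSE }
  if (is.null(adj)) adj <- mate_adjacency(g, active)
  if (is.null(masked_contigs)) masked_contigs <- g$contigs$repeat_flag
  Fe <- edge_labels(g, e)
  le <- g$mate$l[e]; se <- g$mate$sigma[e]
  tol <- params$tol_multiplier
  u0 <- g$mate$u[e]; v0 <- g$mate$v[e]
  comp_e <- if (!is.null(mate_comp)) mate_comp[e] else NA_integer_
  long_edge <- le >= params$long_edge_bp
  best <- NULL
  n_found <- 0L
  iters <- 0L
  capped <- FALSE
  # labels precomputed lazily
  visited_ctg <- rep(FALSE, nrow(g$contigs))
  visited_ctg[v_contig(u0)] <- TRUE  # endpoints' own contigs not traversed
  visited_ctg[v_contig(v0)] <- TRUE
  path_edges <- integer(0)
  path_ctgs <- integer(0)
  hits_for <- function(edges) {
    s <- 0L
    for (me in edges) {
      mr <- g$mate_reads[[me]]
      s <- s + sum(mr$npairs[mr$read %in% Fe])
    }
    s
  }
  dfs <- function(cur, lacc, vacc, nvert) {
    if (n_found >= params$max_paths_long && long_edge) return()
    for (me in adj[[cur]]) {
      if (iters >= iter_budget) { capped <<- TRUE; return() }
      if (me == e || !active[me]) next
      if (!is.na(comp_e) && mate_comp[me] != comp_e) next
      iters <<- iters + 1L
      w2 <- if (g$mate$u[me] == cur) g$mate$v[me] else if
        (g$mate$v[me] == cur) g$mate$u[me] else next
      if (!is_subset(Fe, edge_labels(g, me))) next
      l2 <- lacc + g$mate$l[me]
      v2 <- vacc + g$mate$sigma[me]^2
      if (w2 == v0) {
        sp <- sqrt(v2)
        if (abs(le - l2) <= tol * max(se, sp)) {
          cand_edges <- c(path_edges, me)
          h <- hits_for(cand_edges)
          n_found <<- n_found + 1L
          if (is.null(best) || h > best$hits) {
            best <<- list(mate_edges = cand_edges, contig_ids = path_ctgs,
                          l = l2, sigma = sp, hits = h)
          }
        }
        next
      }
      ctg <- v_contig(w2)
      if (visited_ctg[ctg] || masked_contigs[ctg]) next
      if (!is_subset(Fe, g$contig_labels[[ctg]])) next
      l3 <- l2 + g$contigs$len[ctg]
      if (nvert + 2L > params$max_path_vertices) next
      if (l3 > le && abs(le - l3) > tol * max(se, sqrt(v2))) next
      visited_ctg[ctg] <<- TRUE
      path_edges <<- c(path_edges, me)
      path_ctgs <<- c(path_ctgs, ctg)
      dfs(v_partner(w2), l3, v2, nvert + 2L)
      visited_ctg[ctg] <<- FALSE
      path_edges <<- path_edges[-length(path_edges)]
      path_ctgs <<- path_ctgs[-length(path_ctgs)]
    }
  }
  dfs(u0, 0, 0, 1L)
  if (!is.null(best)) {
    best$iterations <- iters
    best$capped <- capped
    return(best)
  }
  if (capped) return(structure(list(), capped = TRUE))
  NULL
}

#' Transitive reduction of mate edges along long-read-coherent paths
#'
#' Processes mate edges in ascending length; each edge with a coherent path
#' is removed, its weight added to every mate edge of the chosen path, and
#' the (edge, path) record stored in the path database for backbone
#' validation and polishing. Total mate-edge weight is conserved.
#'
#' @param g an [build_ssg] object with repeats masked.
#' @param params a [reduction_params].
#' @return list with `g` (reduced: `mate$removed` flag set, weights
#'   updated) and `path_db` (data.frame: edge, u, v, l_e, sigma_e, l_p,
#'   sigma_p, n_edges, plus list columns `mate_edges`, `reads`).
#' @export
transitive_reduce <- function(g, params = reduction_params()) {
  m <- nrow(g$mate)
  g$mate$removed <- rep(FALSE, m)
  bc <- ssg_biconnected(g)
  ord <- order(g$mate$l, g$mate$id)
  db <- list()
  adj <- mate_adjacency(g, rep(TRUE, m))
  for (e in ord) {
    if (g$mate$removed[e]) next
    active <- !g$mate$removed
    active[e] <- FALSE
    res <- coherent_paths(g, e, params, adj = adj, mate_comp = bc$mate_comp,
                          active = active)
    if (is.null(res) || length(res) == 0) next
    g$mate$removed[e] <- TRUE
    g$mate$w[res$mate_edges] <- g$mate$w[res$mate_edges] + g$mate$w[e]
    db[[length(db) + 1]] <- data.frame(
      edge = e, u = g$mate$u[e], v = g$mate$v[e],
      l_e = g$mate$l[e], sigma_e = g$mate$sigma[e],
      l_p = res$l, sigma_p = res$sigma, n_edges = length(res$mate_edges),
      hits = res$hits)
    db[[length(db)]]$mate_edges <- I(list(res$mate_edges))
    db[[length(db)]]$reads <- I(list(edge_labels(g, e)))
  }
  path_db <- if (length(db)) do.call(rbind, db) else
    data.frame(edge = integer(), u = integer(), v = integer(),
               l_e = numeric(), sigma_e = numeric(), l_p = numeric(),
               sigma_p = numeric(), n_edges = integer(), hits = integer())
  list(g = g, path_db = path_db)
}
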