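# independent brute-force oracles shared by the test files

# exhaustive optimal matching by recursion over edges
brute_matching <- function(u, v, w) {
  best <- 0
  n <- length(u)
  rec <- function(i, usedv, acc) {
    if (i > n) { best <<- max(best, acc); return() }
    rec(i + 1L, usedv, acc)
    if (!(u[i] %in% usedv) && !(v[i] %in% usedv)) {
      rec(i + 1L, c(usedv, u[i], v[i]), acc + w[i])
    }
  }
  rec(1L, integer(0), 0)
  best
}

# brute-force articulation vertices: v is an articulation vertex iff its
# removal increases the number of connected components
brute_articulation <- function(edges, nv) {
  ig <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nv - igraph::vcount(ig)))
  base_comp <- igraph::components(ig)$no
  arts <- integer(0)
  for (v in seq_len(nv)) {
    h <- igraph::delete_vertices(ig, v)
    if (igraph::components(h)$no > base_comp) arts <- c(arts, v)
  }
  arts
}
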