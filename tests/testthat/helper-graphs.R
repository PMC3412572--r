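# small fixture graphs, built in code
triangle_graph <- function() igraph::make_ring(3)
square_graph <- function() igraph::make_ring(4)
ring_graph <- function(n) igraph::make_ring(n)
path3_graph <- function() igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
star5_graph <- function() igraph::make_star(5, mode = "undirected", center = 1)

# random simple graph for property tests (directed or undirected)
random_test_graph <- function(n, density, directed = FALSE) {
  npairs <- if (directed) n * (n - 1) else n * (n - 1) / 2
  m <- max(1L, round(density * npairs))
  if (directed) {
    pairs <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
    pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
    igraph::add_edges(igraph::make_empty_graph(n, directed = TRUE),
                      as.vector(t(pick)))
  } else {
    igraph::sample_gnm(n, m, directed = FALSE)
  }
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!igraph::is_directed(g)) el <- t(apply(el, 1, sort))
  sorted <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste(sorted[, 1], sorted[, 2])
}

# all pendant-attachment compositions with `total` pendants over `k` cycle
# nodes, at most `cap` pendants per node
pendant_compositions <- function(total, k, cap = 2L) {
  grid <- expand.grid(rep(list(0:cap), k))
  grid[rowSums(grid) == total, , drop = FALSE]
}
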