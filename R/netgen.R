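#' @importFrom stats runif rbinom sd cor
#' @importFrom utils write.table
NULL

#' Generate an Erdős–Rényi G(N, M) benchmark graph
#'
#' Draws an undirected simple graph with exactly `n_nodes` nodes and exactly
#' `n_links` edges chosen uniformly at random among all node pairs
#' (the G(N, M) ensemble). The benchmark ensembles used throughout the
#' package have 60 nodes and 250--800 links.
#'
#' @param n_nodes number of nodes.
#' @param n_links number of edges; must not exceed `n_nodes*(n_nodes-1)/2`.
#' @param seed integer seed; the same seed always yields the same edge set.
#' @return an undirected [igraph::igraph] object.
#' @export
generate_er <- function(n_nodes, n_links, seed) {
  max_links <- n_nodes * (n_nodes - 1) / 2
  if (n_links < 0 || n_links > max_links)
    stop("n_links must be between 0 and ", max_links, " for ", n_nodes, " nodes")
  set.seed(seed)
  igraph::sample_gnm(n_nodes, n_links, directed = FALSE)
}

#' Generate a Barabási–Albert scale-free benchmark graph
#'
#' Preferential attachment starting from `m` isolated seed nodes; each of the
#' remaining `n_nodes - m` nodes attaches to `m` distinct existing nodes with
#' probability proportional to their degree, giving exactly `(n_nodes - m) * m`
#' edges. The attachment parameter `m` is chosen so that this count matches
#' `n_links` as closely as possible (the 60-node / 800-link benchmark
#' corresponds to m = 20).
#'
#' @inheritParams generate_er
#' @return an undirected igraph with graph attributes `m` and
#'   `achieved_links` recording the attachment parameter and realised edge
#'   count.
#' @export
generate_ba <- function(n_nodes, n_links, seed) {
  if (n_nodes < 2) stop("need at least 2 nodes")
  m_cand <- seq_len(n_nodes - 1)
  counts <- (n_nodes - m_cand) * m_cand
  best <- which.min(abs(counts - n_links))
  m <- m_cand[best]
  achieved <- counts[best]
  if (abs(achieved - n_links) > 0.05 * n_links)
    stop("no attachment parameter m yields an edge count within 5% of ",
         n_links, " (closest: m=", m, " with ", achieved, " edges)")
  set.seed(seed)
  targets <- seq_len(m)
  repeated <- integer(0)
  edges <- vector("list", n_nodes - m)
  for (v in seq(m + 1, n_nodes)) {
    edges[[v - m]] <- rbind(rep.int(v, m), targets)
    repeated <- c(repeated, targets, rep.int(v, m))
    # next target set: m distinct nodes sampled degree-proportionally
    ts <- integer(0)
    while (length(ts) < m) {
      x <- repeated[sample.int(length(repeated), 1L)]
      if (!x %in% ts) ts <- c(ts, x)
    }
    targets <- ts
  }
  el <- matrix(unlist(edges), nrow = 2)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(el))
  g <- igraph::set_graph_attr(g, "m", m)
  igraph::set_graph_attr(g, "achieved_links", achieved)
}

#' Generate a random-modular benchmark graph
#'
#' Composition of `n_modules` equal-size Erdős–Rényi blocks with a small
#' number of links between blocks: `n_links - inter_links` edges are split
#' evenly across the modules (each module an independent uniform draw) and
#' `inter_links` edges connect random node pairs in distinct modules. If the
#' even intra-module quota exceeds a module's capacity `s*(s-1)/2`, modules
#' are filled to capacity and the overflow spills into the inter-module pool,
#' so that the total edge count always equals `n_links` (the 60-node /
#' 800-link / 4-module benchmark is only realisable this way: complete
#' 15-node modules plus 380 cross links).
#'
#' @inheritParams generate_er
#' @param n_modules number of equal-size modules; must divide `n_nodes`.
#' @param inter_links requested number of links between distinct modules
#'   (default 5% of `n_links`).
#' @return an undirected igraph with a per-node `module` vertex attribute
#'   (1-based module index).
#' @export
generate_modular <- function(n_nodes, n_links, n_modules,
                             inter_links = round(0.05 * n_links), seed) {
  if (n_nodes %% n_modules != 0)
    stop("n_modules must divide n_nodes")
  if (inter_links >= n_links && n_links > 0)
    stop("inter_links must be smaller than n_links")
  s <- n_nodes %/% n_modules
  cap <- s * (s - 1) / 2
  membership <- rep(seq_len(n_modules), each = s)
  intra_total <- n_links - inter_links
  quota <- rep(intra_total %/% n_modules, n_modules)
  extra <- intra_total %% n_modules
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  spill <- sum(pmax(quota - cap, 0))
  quota <- pmin(quota, cap)
  inter_total <- inter_links + spill
  cross_cap <- n_nodes * (n_nodes - 1) / 2 - n_modules * cap
  if (inter_total > cross_cap)
    stop("requested link count exceeds graph capacity: need ", inter_total,
         " inter-module links but only ", cross_cap, " pairs exist")
  set.seed(seed)
  edges <- integer(0)
  pairs_of <- function(nodes) {
    if (length(nodes) < 2) return(matrix(integer(0), nrow = 2))
    utils::combn(nodes, 2)
  }
  for (mod in seq_len(n_modules)) {
    nodes <- which(membership == mod)
    pr <- pairs_of(nodes)
    pick <- sample.int(ncol(pr), quota[mod])
    edges <- c(edges, as.vector(pr[, pick, drop = FALSE]))
  }
  if (inter_total > 0) {
    all_pairs <- pairs_of(seq_len(n_nodes))
    cross <- membership[all_pairs[1, ]] != membership[all_pairs[2, ]]
    pr <- all_pairs[, cross, drop = FALSE]
    pick <- sample.int(ncol(pr), inter_total)
    edges <- c(edges, as.vector(pr[, pick, drop = FALSE]))
  }
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  g <- igraph::add_edges(g, edges)
  igraph::set_vertex_attr(g, "module", value = membership)
}

#' Read a graph from a plain-text file
#'
#' Supported dialects:
#' * `edgelist`: two whitespace-separated columns of 0-based integer node
#'   ids, one edge per line, undirected edges listed once; lines starting
#'   with `#` are ignored.
#' * `adjacency`: dense whitespace-separated 0/1 matrix, N rows by
#'   N columns, no header; the diagonal must be zero and the matrix must be
#'   symmetric unless `directed = TRUE`.
#' * `graphml`: via igraph; a `module` node attribute is preserved.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"adjacency"`, `"graphml"`.
#' @param directed logical; for `edgelist`/`adjacency`, whether to build a
#'   directed graph.
#' @param n_nodes optional node count for edge lists whose highest ids are
#'   isolated.
#' @return an igraph object.
#' @export
read_network <- function(path, format = c("edgelist", "adjacency", "graphml"),
                         directed = FALSE, n_nodes = NULL) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  if (format == "edgelist") {
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    parse_one <- function(i) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      ids <- suppressWarnings(as.integer(parts))
      if (length(ids) != 2 || anyNA(ids) || any(ids < 0))
        stop("malformed edge list at line ", i, ": '", lines[i], "'")
      ids
    }
    el <- vapply(idx, parse_one, integer(2))
    n <- if (is.null(n_nodes)) {
      if (length(el)) max(el) + 1L else 0L
    } else n_nodes
    if (length(el) && max(el) + 1L > n)
      stop("edge list refers to node ", max(el), " but n_nodes = ", n)
    if (length(el)) {
      ev <- as.vector(el) + 1L
      self <- el[1, ] == el[2, ]
      if (any(self))
        stop("self-loop at line ", idx[which(self)[1]])
    } else ev <- integer(0)
    g <- igraph::make_empty_graph(n, directed = directed)
    return(igraph::add_edges(g, ev))
  }
  # adjacency
  rows <- lapply(seq_along(lines), function(i) {
    if (!nzchar(trimws(lines[i]))) return(NULL)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric adjacency entry at line ", i)
    vals
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  n <- length(rows)
  lens <- lengths(rows)
  if (any(lens != n))
    stop("adjacency matrix not square: line ", which(lens != n)[1],
         " has ", lens[lens != n][1], " columns, expected ", n)
  A <- do.call(rbind, rows)
  if (!all(A %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(A) != 0))
    stop("nonzero diagonal at row ", which(diag(A) != 0)[1], " (self-loops not allowed)")
  if (!directed && !isTRUE(all.equal(A, t(A))))
    stop("asymmetric adjacency matrix but directed = FALSE requested")
  igraph::graph_from_adjacency_matrix(A, mode = if (directed) "directed" else "undirected")
}

#' Write a graph to a plain-text file
#'
#' Inverse of [read_network()]: `write_network` then `read_network` (and
#' vice versa) are identities on the edge set.
#'
#' @param graph an igraph object.
#' @inheritParams read_network
#' @export
write_network <- function(graph, path, format = c("edgelist", "adjacency", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "edgelist") {
    el <- igraph::as_edgelist(graph, names = FALSE) - 1L
    writeLines(sprintf("%d %d", el[, 1], el[, 2]), path)
  } else {
    A <- binary_adjacency(graph)
    writeLines(apply(A, 1, paste, collapse = " "), path)
  }
  invisible(NULL)
}

#' Order nodes by decreasing degree
#'
#' Permutation used to sort adjacency and co-activation matrices from high
#' to low degree; ties are broken by ascending node index so orderings are
#' reproducible.
#'
#' @param graph an igraph object.
#' @return integer permutation of `1:N` with non-increasing degree.
#' @export
sort_by_degree <- function(graph) {
  d <- igraph::degree(graph, mode = "all")
  order(-d, seq_along(d))
}

#' Iteratively remove the highest-degree nodes
#'
#' Removes `k` nodes one at a time, at each step deleting the current
#' highest-degree node together with all its edges (degrees are recomputed
#' between removals; ties go to the lowest node index).
#'
#' @param graph an igraph object.
#' @param k number of hubs to remove; must be smaller than the node count.
#' @return the reduced igraph (with `N - k` nodes).
#' @export
remove_hubs <- function(graph, k) {
  if (k >= igraph::vcount(graph)) stop("k must be smaller than the node count")
  for (i in seq_len(k)) {
    d <- igraph::degree(graph, mode = "all")
    graph <- igraph::delete_vertices(graph, which.max(d))
  }
  graph
}

# dense 0/1 adjacency matrix of an igraph (multi-edges collapsed)
binary_adjacency <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  A[A > 0] <- 1
  storage.mode(A) <- "double"
  unname(A)
}
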