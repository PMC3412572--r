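# Exact elementary-cycle counting.
#
# C(n) = Tr(B^(n)) / n, where B^(n)_ij is the number of n-step paths from i
# to j whose n-1 interior nodes are pairwise distinct and distinct from i and
# j. B^(1) = A and B^(2) = A^2 (whose diagonal equals the degrees but is
# never consumed, since every trace step multiplies by A_ki and A_ii = 0).
# For n >= 4 the loop-free path counts are assembled from auxiliary matrices
# D^(q | a1..az) counting q-step paths that avoid an excluded node set:
#
#   D^(2 | a..)_ik = sum_{x not excluded} A_ix A_xk
#   D^(q | a..)_ik = sum_{x not excluded, x != i} D^(q-1 | a.., k)_ix A_xk
#   B^(n-1)_ik     = sum_{y != i} D^(n-2 | k)_iy A_yk
#
# The D family is memoized by (q, sorted exclusion set); the number of
# exclusion sets grows combinatorially with the maximum cycle length, hence
# the hard cap on n.

MAX_CYCLE_LENGTH <- 7L

#' Count elementary cycles by the end-constrained recursion
#'
#' Exact oriented elementary-cycle counts C(n) for n = 3 .. `max_length`,
#' computed from trace formulas over loop-free path-count matrices (no cycle
#' listing). Works for directed and undirected graphs; on undirected graphs
#' every cycle is counted once per traversal orientation, so all C(n) are
#' even (see [undirected_correction()]).
#'
#' @param graph an igraph object (directed or undirected).
#' @param max_length largest cycle length to count; between 3 and 7 (the
#'   memoized exclusion-set family grows combinatorially with this cap).
#' @return a `cycle_census`: list with `oriented_counts` (named vector,
#'   names "3".."max_length"), `max_length`, `directed`.
#' @export
count_elementary_cycles <- function(graph, max_length = 4L) {
  max_length <- as.integer(max_length)
  if (max_length < 3L || max_length > MAX_CYCLE_LENGTH)
    stop("max_length must be between 3 and ", MAX_CYCLE_LENGTH)
  A <- binary_adjacency(graph)
  N <- nrow(A)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  getD <- function(q, excl) {
    key <- paste0(q, "|", paste(excl, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    keep <- setdiff(seq_len(N), excl)
    if (q == 2L) {
      M <- A[, keep, drop = FALSE] %*% A[keep, , drop = FALSE]
    } else {
      M <- matrix(0, N, N)
      for (k in seq_len(N)) {
        v <- getD(q - 1L, sort(unique(c(excl, k))))
        col <- as.vector(v[, keep, drop = FALSE] %*% A[keep, k])
        # drop the x = i term (kept only where i itself is not excluded)
        col[keep] <- col[keep] - diag(v)[keep] * A[keep, k]
        M[, k] <- col
      }
    }
    memo[[key]] <- M
    M
  }
  counts <- numeric(0)
  for (n in 3:max_length) {
    if (n == 3L) {
      total <- sum(diag(A %*% A %*% A))
    } else {
      total <- 0
      for (k in seq_len(N)) {
        D <- getD(n - 2L, k)
        colk <- as.vector(D %*% A[, k]) - diag(D) * A[, k]  # B^(n-1)[, k]
        total <- total + sum(colk * A[k, ])
      }
    }
    cn <- total / n
    if (abs(cn - round(cn)) > 1e-9)
      stop("internal error: non-integer cycle count for n = ", n)
    counts[as.character(n)] <- round(cn)
  }
  structure(list(oriented_counts = counts, max_length = max_length,
                 directed = igraph::is_directed(graph)),
            class = "cycle_census")
}

#' Brute-force elementary-cycle census (oracle)
#'
#' Exhaustive depth-first enumeration of oriented elementary cycles with
#' canonical-start deduplication: every cycle is generated exactly once as a
#' walk starting (and ending) at its minimum-index node and otherwise
#' visiting only higher-index nodes. Intended for small graphs as an
#' independent check of [count_elementary_cycles()].
#'
#' @inheritParams count_elementary_cycles
#' @return a `cycle_census`.
#' @export
brute_force_census <- function(graph, max_length = 4L) {
  max_length <- as.integer(max_length)
  if (max_length < 3L) stop("max_length must be >= 3")
  N <- igraph::vcount(graph)
  mode <- if (igraph::is_directed(graph)) "out" else "all"
  nbrs <- lapply(seq_len(N), function(v)
    sort(unique(as.integer(igraph::neighbors(graph, v, mode = mode)))))
  counts <- stats::setNames(numeric(max_length - 2L), as.character(3:max_length))
  visited <- logical(N)
  dfs <- function(start, v, depth) {
    for (w in nbrs[[v]]) {
      if (w == start) {
        if (depth >= 3L) {
          key <- as.character(depth)
          counts[key] <<- counts[key] + 1
        }
      } else if (w > start && !visited[w] && depth < max_length) {
        visited[w] <<- TRUE
        dfs(start, w, depth + 1L)
        visited[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(N)) {
    visited[s] <- TRUE
    dfs(s, s, 1L)
    visited[s] <- FALSE
  }
  structure(list(oriented_counts = counts, max_length = max_length,
                 directed = igraph::is_directed(graph)),
            class = "cycle_census")
}

#' Undirected cycle-count correction
#'
#' On an undirected graph the oriented counts include both traversal
#' directions of every elementary cycle, so the number of undirected cycles
#' is C(n)/2 for every n >= 3 (the triangle K3 already yields an oriented
#' count of 2 for its single undirected triangle). An odd oriented count on
#' an undirected graph violates this parity and raises an error.
#'
#' @param census a `cycle_census` from an undirected graph.
#' @return the census with an `undirected_counts` component added.
#' @export
undirected_correction <- function(census) {
  if (isTRUE(census$directed))
    stop("undirected correction applies to undirected graphs only")
  if (any(census$oriented_counts %% 2 != 0))
    stop("parity violation: odd oriented cycle count on an undirected graph")
  census$undirected_counts <- census$oriented_counts / 2
  census
}

#' @export
print.cycle_census <- function(x, ...) {
  cat("Elementary cycle census (",
      if (x$directed) "directed" else "undirected", " graph):\n", sep = "")
  for (n in names(x$oriented_counts)) {
    cat("  C(", n, ") = ", x$oriented_counts[[n]], sep = "")
    if (!is.null(x$undirected_counts))
      cat("  [", x$undirected_counts[[n]], " undirected]", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Write a cycle census as JSON or TSV
#'
#' @param census a `cycle_census`.
#' @param file output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_census <- function(census, file, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.list(census$oriented_counts), file,
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(n = as.integer(names(census$oriented_counts)),
                     oriented = unname(census$oriented_counts))
    if (!is.null(census$undirected_counts))
      df$undirected <- unname(census$undirected_counts)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
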