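#' Co-activation counts over a periodic orbit
#'
#' Counts, for every ordered node pair, how often the pair is jointly excited
#' over one full periodic orbit of a sustained trajectory. With `delay = 0`
#' entry (i, j) counts time steps at which i and j are excited
#' simultaneously (a symmetric matrix). With `delay = 1` entry (i, j) counts
#' steps at which i is excited at t+1 and j at t, accumulated cyclically
#' around the orbit so the result does not depend on any observation-window
#' length; the delay -1 matrix is its transpose.
#'
#' @param traj a sustained `ser_trajectory`.
#' @param delay 0 or 1.
#' @return a `coactivation_matrix`: numeric N-by-N count matrix with
#'   attributes `delay`, `normalized = FALSE`, `n_runs = 1` and
#'   `excitations` (per-node excitation counts over the same orbit).
#' @export
coactivation_counts <- function(traj, delay = 0) {
  if (traj$fate != "sustained")
    stop("trajectory is extinct: the orbit contains no excitations")
  if (!delay %in% c(0, 1)) stop("delay must be 0 or 1")
  E <- orbit_states(traj) == 1L
  storage.mode(E) <- "double"
  counts <- if (delay == 0) {
    crossprod(E)
  } else {
    p <- nrow(E)
    crossprod(E[c(seq_len(p)[-1], 1L), , drop = FALSE], E)
  }
  structure(unname(counts), delay = delay, normalized = FALSE, n_runs = 1L,
            excitations = unname(colSums(E)), class = "coactivation_matrix")
}

#' Min-normalize a co-activation count matrix
#'
#' Divides each pair count by the minimum of the two nodes' excitation
#' counts over the same orbit; pairs involving a never-excited node are set
#' to 0. Normalized values lie in `[0, 1]`.
#'
#' @param counts raw `coactivation_matrix` from [coactivation_counts()].
#' @param excitations per-node excitation counts; defaults to the counts
#'   recorded in the matrix.
#' @return a normalized `coactivation_matrix`.
#' @export
normalize_coactivation <- function(counts, excitations = attr(counts, "excitations")) {
  if (isTRUE(attr(counts, "normalized"))) stop("matrix is already normalized")
  n <- nrow(counts)
  mins <- outer(excitations, excitations, pmin)
  vals <- ifelse(mins > 0, counts / mins, 0)
  structure(unname(vals), delay = attr(counts, "delay"), normalized = TRUE,
            n_runs = attr(counts, "n_runs"), class = "coactivation_matrix")
}

#' Average co-activation matrix over random initial conditions
#'
#' Simulates the SER dynamics from `n_init` random initial conditions
#' (excitation probability `p_excite`, S/R equipartition) and averages the
#' min-normalized co-activation matrices of the runs that reach sustained
#' activity; extinct runs are discarded.
#'
#' @param graph an igraph object.
#' @param n_init number of initial conditions (benchmark value 500).
#' @param delay 0 or 1.
#' @param p_excite excitation probability of the initial conditions.
#' @param seed integer seed for the whole batch.
#' @param config a [ser_config()].
#' @return a normalized `coactivation_matrix` with attribute `n_runs` set to
#'   the number of sustained runs averaged.
#' @export
average_coactivation <- function(graph, n_init = 500, delay = 0,
                                 p_excite = 0.1, seed = 1L,
                                 config = ser_config()) {
  if (n_init < 1) stop("n_init must be >= 1")
  set.seed(seed)
  n <- igraph::vcount(graph)
  P <- propagation_matrix(graph)
  acc <- matrix(0, n, n)
  sustained <- 0L
  for (i in seq_len(n_init)) {
    init <- encode_state(random_initial_state(n, p_excite), config$r)
    traj <- run_core(P, init, config$r, config$max_steps)
    if (traj$fate != "sustained") next
    sustained <- sustained + 1L
    acc <- acc + normalize_coactivation(coactivation_counts(traj, delay))
  }
  if (sustained == 0L)
    stop("no sustained activity in any of the ", n_init, " runs")
  structure(acc / sustained, delay = delay, normalized = TRUE,
            n_runs = sustained, class = "coactivation_matrix")
}

#' Threshold and binarize a co-activation matrix
#'
#' Entries strictly exceeding the threshold become 1, all others 0; the
#' diagonal is forced to 0. The connection density is the number of ones
#' divided by the number of off-diagonal entries, N^2 - N.
#'
#' @param matrix a normalized `coactivation_matrix` (any numeric matrix is
#'   accepted).
#' @param threshold the threshold.
#' @return a 0/1 matrix with attribute `density`.
#' @export
binarize <- function(matrix, threshold) {
  B <- (unclass(matrix) > threshold) + 0
  diag(B) <- 0
  n <- nrow(B)
  structure(B, density = sum(B) / (n^2 - n))
}

#' Connection density of a binarized matrix
#'
#' @param binary a matrix from [binarize()].
#' @return ones / (N^2 - N).
#' @export
connection_density <- function(binary) {
  d <- attr(binary, "density")
  if (!is.null(d)) return(d)
  n <- nrow(binary)
  sum(binary[row(binary) != col(binary)]) / (n^2 - n)
}

# Pearson correlation of two numeric vectors with a zero-variance sentinel
cor_or_na <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Correlation between a binarized functional matrix and the adjacency
#'
#' Pearson correlation over the N^2 - N off-diagonal entries of the binary
#' matrix and the structural adjacency matrix. When either flattened
#' sequence has zero variance (e.g., at extreme thresholds) the result is
#' `NA` rather than an error.
#'
#' @param binary a 0/1 matrix (e.g., from [binarize()]).
#' @param graph the structural igraph.
#' @return a correlation coefficient, or `NA`.
#' @export
adjacency_correlation <- function(binary, graph) {
  A <- binary_adjacency(graph)
  if (!all(dim(binary) == dim(A))) stop("matrix dimensions do not match the graph")
  off <- row(A) != col(A)
  cor_or_na(as.vector(unclass(binary)[off]), A[off])
}

#' Null correlation of random binary sequences
#'
#' Mean and standard deviation of the Pearson correlation between pairs of
#' independent equiprobable binary sequences of length N^2 - N, used as a
#' baseline for the structure-function correlation curves.
#'
#' @param n_nodes matrix dimension N.
#' @param n_sequences number of replicate pairs (benchmark value 1000).
#' @param seed optional integer seed.
#' @return named vector `c(mean, sd)`.
#' @export
random_baseline <- function(n_nodes, n_sequences = 1000, seed = NULL) {
  if (n_sequences < 2) stop("n_sequences must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  len <- n_nodes^2 - n_nodes
  rs <- vapply(seq_len(n_sequences), function(i) {
    cor_or_na(rbinom(len, 1, 0.5), rbinom(len, 1, 0.5))
  }, numeric(1))
  c(mean = mean(rs, na.rm = TRUE), sd = sd(rs, na.rm = TRUE))
}

#' Structure-function correlation across thresholds
#'
#' For each threshold, binarizes the (normalized, averaged) co-activation
#' matrix and records the connection density, the Pearson correlation with
#' the structural adjacency matrix, and the random-sequence baseline.
#'
#' @param matrix a normalized `coactivation_matrix`.
#' @param graph the structural igraph.
#' @param thresholds threshold grid (default 0 to 1 in steps of 0.02).
#' @param n_baseline number of baseline sequence pairs.
#' @param seed optional seed for the baseline draw.
#' @return a `threshold_curve` data frame with columns `threshold`,
#'   `density`, `correlation`, `baseline_mean`, `baseline_sd`.
#' @export
threshold_sweep <- function(matrix, graph, thresholds = seq(0, 1, by = 0.02),
                            n_baseline = 1000, seed = NULL) {
  base <- random_baseline(nrow(matrix), n_baseline, seed)
  rows <- lapply(thresholds, function(th) {
    B <- binarize(matrix, th)
    data.frame(threshold = th, density = attr(B, "density"),
               correlation = adjacency_correlation(B, graph))
  })
  out <- do.call(rbind, rows)
  out$baseline_mean <- base["mean"]
  out$baseline_sd <- base["sd"]
  rownames(out) <- NULL
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' @export
print.coactivation_matrix <- function(x, ...) {
  cat("Co-activation matrix:", nrow(x), "nodes, delay", attr(x, "delay"),
      if (isTRUE(attr(x, "normalized"))) "(normalized)" else "(raw counts)",
      "\n")
  cat("  averaged over", attr(x, "n_runs"), "sustained run(s)\n")
  invisible(x)
}

#' Write a matrix (co-activation or binary) as TSV
#'
#' @param matrix a numeric matrix.
#' @param file output path.
#' @param labels optional column labels written as a header line.
#' @export
write_matrix_tsv <- function(matrix, file, labels = NULL) {
  utils::write.table(unclass(matrix), file, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = if (is.null(labels)) FALSE else labels)
  invisible(NULL)
}
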