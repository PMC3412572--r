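# Exhaustive basin-of-attraction analysis for small cyclic "devices":
# an elementary cycle (triangle, square, ...) optionally embedded in a local
# neighbourhood by attaching pendant nodes to its cycle nodes.

#' Specify a small cyclic device with pendant attachments
#'
#' Builds a ring of `cycle_length` nodes (numbered 1 .. cycle_length, in
#' cycle order) and attaches `attachments[i]` pendant nodes to cycle node i.
#' A triangle with pendants of up to two per vertex covers the embeddings
#' with 5-7 nodes and cycle-node degree 2-4.
#'
#' @param cycle_length length of the device cycle (>= 3).
#' @param attachments integer vector of pendant counts, one per cycle node
#'   (default: none).
#' @return a `device_spec`: list with `graph` (igraph), `cycle_nodes`,
#'   `attachments`.
#' @export
device_spec <- function(cycle_length, attachments = integer(cycle_length)) {
  if (cycle_length < 3) stop("cycle_length must be >= 3")
  if (length(attachments) != cycle_length)
    stop("attachments must give one pendant count per cycle node")
  if (any(attachments < 0)) stop("pendant counts must be non-negative")
  n <- cycle_length + sum(attachments)
  g <- igraph::make_ring(cycle_length, directed = FALSE)
  g <- igraph::add_vertices(g, sum(attachments))
  nxt <- cycle_length + 1L
  for (i in seq_len(cycle_length)) {
    for (j in seq_len(attachments[i])) {
      g <- igraph::add_edges(g, c(i, nxt))
      nxt <- nxt + 1L
    }
  }
  role <- c(rep("cycle", cycle_length), rep("pendant", sum(attachments)))
  g <- igraph::set_vertex_attr(g, "role", value = role)
  structure(list(graph = g, cycle_nodes = seq_len(cycle_length),
                 attachments = as.integer(attachments)),
            class = "device_spec")
}

#' Materialize a device as a graph
#'
#' @param device a `device_spec`.
#' @return the device igraph (cycle-node identity preserved in the vertex
#'   attribute `role` and by position: cycle nodes come first, in cycle
#'   order).
#' @export
make_embedding <- function(device) {
  if (!inherits(device, "device_spec")) stop("device must be a device_spec")
  device$graph
}

# decode state index (0 .. 3^k-1) to a label vector over S/E/R
index_to_labels <- function(idx, k) {
  digits <- integer(k)
  for (j in seq_len(k)) {
    digits[j] <- idx %% 3L
    idx <- idx %/% 3L
  }
  c("S", "E", "R")[digits + 1L]
}

#' Exhaustive fate enumeration for a small device
#'
#' Simulates every one of the 3^k initial conditions of the device
#' (optionally restricted to those with at least one excitation) to its
#' recurrence and tabulates the asymptotic fate, orbit period and transient
#' length, plus aggregate sustained counts stratified by the number of
#' initial excitations.
#'
#' @param device a `device_spec` or an igraph object.
#' @param config a [ser_config()].
#' @param require_excitation if TRUE, skip initial conditions without any
#'   excited node (they are trivially extinct).
#' @return a `fate_table` data frame with columns `state` (string over
#'   S/E/R), `n_excited`, `fate`, `period`, `transient`, and attributes
#'   `n_sustained`, `by_excitations` (sustained counts per initial
#'   excitation number).
#' @export
enumerate_fates <- function(device, config = ser_config(),
                            require_excitation = FALSE) {
  g <- if (inherits(device, "device_spec")) device$graph else device
  k <- igraph::vcount(g)
  if (k > 12) stop("device too large for exhaustive 3^k enumeration (k <= 12)")
  P <- propagation_matrix(g)
  total <- 3L^k
  rows <- vector("list", total)
  kept <- 0L
  for (idx in seq_len(total) - 1L) {
    labels <- index_to_labels(idx, k)
    n_exc <- sum(labels == "E")
    if (require_excitation && n_exc == 0L) next
    traj <- run_core(P, encode_state(labels, config$r), config$r,
                     config$max_steps)
    kept <- kept + 1L
    rows[[kept]] <- data.frame(
      state = paste(labels, collapse = ""), n_excited = n_exc,
      fate = traj$fate, period = traj$period, transient = traj$transient,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(kept)])
  sus <- out$fate == "sustained"
  by_exc <- table(factor(out$n_excited[sus], levels = 0:k))
  attr(out, "n_sustained") <- sum(sus)
  attr(out, "by_excitations") <- by_exc
  attr(out, "device_nodes") <- k
  class(out) <- c("fate_table", "data.frame")
  out
}

# all cyclic rotations of a state string, as strings
rotations_of <- function(state_string) {
  chars <- strsplit(state_string, "")[[1]]
  L <- length(chars)
  vapply(seq_len(L) - 1L, function(s)
    paste(chars[((seq_len(L) - 1L + s) %% L) + 1L], collapse = ""),
    character(1))
}

#' Group device fates by cyclic rotation
#'
#' Collapses the initial conditions of an isolated cycle device into
#' equivalence classes under cyclic rotation of the cycle labelling
#' (reflections are not identified: ESR and ERS, the two orientations of the
#' period-3 pacemaker, remain distinct classes). The fate must be constant
#' within each class; a violation would indicate a dynamics bug and raises
#' an error.
#'
#' @param table a `fate_table` computed on an isolated cycle device.
#' @return data frame with one row per class: `representative` (rotation
#'   minimum), `class_size`, `fate`, `period`.
#' @export
reduce_by_rotation <- function(table) {
  reps <- vapply(table$state, function(s) min(rotations_of(s)), character(1))
  split_idx <- split(seq_len(nrow(table)), reps)
  rows <- lapply(names(split_idx), function(rep) {
    i <- split_idx[[rep]]
    fates <- unique(table$fate[i])
    if (length(fates) != 1)
      stop("internal error: inconsistent fates within rotation class ", rep)
    data.frame(representative = rep, class_size = length(i),
               fate = fates, period = table$period[i][1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# sustained initial-condition strings of the isolated cycle of length L
sustained_cycle_states <- function(L, config = ser_config()) {
  dev <- device_spec(L)
  tab <- enumerate_fates(dev, config)
  tab$state[tab$fate == "sustained"]
}

#' Does the device-cycle initial state predict the fate of the embedding?
#'
#' Exhaustively simulates every initial condition of an embedded device and
#' compares the observed fate against the predictor "the cycle sub-state is
#' one of the isolated cycle's sustained configurations" (for the triangle:
#' a rotation of ESR or ERS). Reports the agreement fraction and every
#' counterexample.
#'
#' @param device a `device_spec` (cycle plus pendant attachments).
#' @param config a [ser_config()].
#' @return a list with `agreement` (fraction in `[0, 1]`), `n_states`,
#'   `counterexamples` (data frame of disagreeing initial conditions) and
#'   `sustained_cycle_states`.
#' @export
basin_invariance_check <- function(device, config = ser_config()) {
  if (!inherits(device, "device_spec")) stop("device must be a device_spec")
  L <- length(device$cycle_nodes)
  good <- sustained_cycle_states(L, config)
  tab <- enumerate_fates(device, config)
  cyc_sub <- substr(tab$state, 1L, L)  # cycle nodes come first, in order
  predicted <- ifelse(cyc_sub %in% good, "sustained", "extinct")
  agree <- predicted == tab$fate
  counterexamples <- tab[!agree, c("state", "n_excited", "fate", "period")]
  counterexamples$predicted <- predicted[!agree]
  rownames(counterexamples) <- NULL
  list(agreement = mean(agree), n_states = nrow(tab),
       counterexamples = counterexamples, sustained_cycle_states = good)
}

#' Scan single external excitations for phase slips
#'
#' Starting from a sustained configuration of an isolated device, applies
#' every possible single perturbation event (one node, one time step within
#' the unperturbed orbit) as a virtual excited neighbour, and reports
#' whether activity persists and after how many steps the initial
#' configuration recurs. Recurrence times shorter than the unperturbed
#' period are phase slips; on the triangle pacemaker no event changes the
#' orbit.
#'
#' @param device a `device_spec`.
#' @param init sustained initial state (labels or codes).
#' @param config a [ser_config()].
#' @return data frame with columns `time`, `node`, `fate`,
#'   `recurrence_time` (NA if the initial configuration never recurs) and
#'   `phase_slip`.
#' @export
phase_slip_scan <- function(device, init, config = ser_config()) {
  g <- if (inherits(device, "device_spec")) device$graph else device
  codes <- if (is.character(init)) encode_state(init, config$r) else as.integer(init)
  base <- ser_run(g, codes, config)
  if (base$fate != "sustained")
    stop("init must be a sustained configuration of the device")
  P0 <- base$period
  n <- igraph::vcount(g)
  grid <- expand.grid(time = seq_len(P0) - 1L, node = seq_len(n))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- data.frame(time = grid$time[i], node = grid$node[i])
    traj <- ser_run_perturbed(g, codes, ev, config)
    rec <- NA_integer_
    # the periodic extension guarantees any recurrence shows up by T + period
    for (t in seq_len(nrow(traj$states) + traj$period)) {
      if (all(state_at(traj, t) == codes)) { rec <- t; break }
    }
    data.frame(time = ev$time, node = ev$node, fate = traj$fate,
               recurrence_time = rec,
               phase_slip = !is.na(rec) && rec < P0)
  })
  out <- do.call(rbind, rows)
  attr(out, "unperturbed_period") <- P0
  out
}

#' @export
print.fate_table <- function(x, ...) {
  cat("Fate table:", nrow(x), "initial conditions on",
      attr(x, "device_nodes"), "nodes;",
      attr(x, "n_sustained"), "sustained\n")
  cat("  sustained by #initial excitations:\n")
  print(attr(x, "by_excitations"))
  invisible(x)
}

#' Write a fate table as TSV
#'
#' @param table a `fate_table`.
#' @param file output path.
#' @export
write_fate_table <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
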