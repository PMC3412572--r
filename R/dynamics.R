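# Internal state encoding: 0 = S, 1 = E, a + 1 = R with `a` steps left before
# regeneration (a in 1..r). With the default refractory period r = 1 the codes
# are simply S=0, E=1, R=2.

#' SER simulation settings
#'
#' @param r deterministic refractory period (steps a node stays R before
#'   regenerating to S); the analyses in this package use r = 1.
#' @param max_steps cap on the recurrence search. The configuration space is
#'   finite so every run recurs; hitting the cap signals it is set too small.
#' @return a list of class `ser_config`.
#' @export
ser_config <- function(r = 1L, max_steps = 30000L) {
  r <- as.integer(r)
  if (r < 1L) stop("refractory period r must be >= 1")
  structure(list(r = r, max_steps = as.integer(max_steps)), class = "ser_config")
}

# labels -> codes; initially-R nodes get the full refractory age r
encode_state <- function(labels, r = 1L) {
  codes <- match(labels, c("S", "E", "R")) - 1L
  if (anyNA(codes)) stop("state labels must be 'S', 'E' or 'R'")
  codes[codes == 2L] <- r + 1L
  codes
}

decode_state <- function(codes) {
  c("S", "E", "R")[pmin(codes, 2L) + 1L]
}

# propagation matrix: P[i, j] = 1 iff an excitation at j reaches i in one step
# (in-neighbours for directed graphs: excitation flows along edge direction)
propagation_matrix <- function(graph) {
  t(binary_adjacency(graph))
}

# one synchronous update on the encoded state vector
step_codes <- function(P, state, r, external = integer(0)) {
  inflow <- as.vector(P %*% (state == 1L)) > 0
  if (length(external)) inflow[external] <- TRUE
  new <- integer(length(state))
  new[state == 0L & inflow] <- 1L
  new[state == 1L] <- r + 1L
  dec <- state > 2L
  new[dec] <- state[dec] - 1L
  # state == 2L (last refractory step) regenerates to S = 0, already the default
  new
}

#' One synchronous SER update
#'
#' Update rules: a susceptible node becomes excited when at least one direct
#' neighbour is excited (in-neighbour on directed graphs) or when it is listed
#' in `external`, which acts as a virtual excited neighbour for this one step;
#' an excited node becomes refractory; a refractory node regenerates to S
#' after `r` steps.
#'
#' @param graph an igraph object.
#' @param state per-node state, as a character vector over `"S"`, `"E"`,
#'   `"R"` or as an integer code vector (0 = S, 1 = E, a+1 = R with a steps
#'   left).
#' @param config a [ser_config()].
#' @param external optional node indices receiving an external excitation
#'   during this update (only susceptible nodes are affected).
#' @return the successor state, in the representation of the input.
#' @export
ser_step <- function(graph, state, config = ser_config(), external = integer(0)) {
  chr <- is.character(state)
  codes <- if (chr) encode_state(state, config$r) else as.integer(state)
  if (length(codes) != igraph::vcount(graph))
    stop("state length does not match the node count")
  out <- step_codes(propagation_matrix(graph), codes, config$r, external)
  if (chr) decode_state(out) else out
}

# core runner on a precomputed propagation matrix.
# events: NULL or data.frame(time, node) with 0-based times; the event at
# time t injects a virtual excited neighbour during the update t -> t+1.
# Recurrence detection starts only once all events have fired, so detected
# periodicity refers to the autonomous dynamics.
run_core <- function(P, state, r, max_steps, events = NULL) {
  n <- length(state)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  states <- list()
  last_event <- if (!is.null(events) && nrow(events) > 0) max(events$time) else -1L
  t <- 0L
  repeat {
    if (t > last_event) {
      key <- paste(state, collapse = ",")
      prev <- seen[[key]]
      if (!is.null(prev)) {
        transient <- prev
        period <- t - prev
        break
      }
      seen[[key]] <- t
    }
    states[[t + 1L]] <- state
    if (t >= max_steps)
      stop("no recurrence within max_steps = ", max_steps,
           "; increase max_steps in ser_config()")
    ext <- if (is.null(events)) integer(0) else events$node[events$time == t]
    state <- step_codes(P, state, r, ext)
    t <- t + 1L
  }
  mat <- do.call(rbind, states)
  orbit <- mat[seq(transient + 1L, transient + period), , drop = FALSE]
  fate <- if (any(orbit == 1L)) "sustained" else "extinct"
  structure(
    list(states = mat, transient = transient, period = period,
         fate = fate, r = r, n_nodes = n),
    class = "ser_trajectory")
}

#' Run the SER automaton to its recurrence
#'
#' Iterates the synchronous update from `init`, recording every full network
#' state, and stops at the first repeated state. The trajectory splits into a
#' transient prefix and a periodic orbit; the run is `"extinct"` when the
#' orbit is the all-susceptible fixed point (the automaton's only fixed
#' point) and `"sustained"` otherwise.
#'
#' @inheritParams ser_step
#' @param init initial state (character labels or integer codes).
#' @return a `ser_trajectory`: list with `states` (rows = states at times
#'   0 .. transient+period-1, integer codes), `transient`, `period`, `fate`.
#' @export
ser_run <- function(graph, init, config = ser_config()) {
  codes <- if (is.character(init)) encode_state(init, config$r) else as.integer(init)
  if (length(codes) != igraph::vcount(graph))
    stop("init length does not match the node count")
  run_core(propagation_matrix(graph), codes, config$r, config$max_steps)
}

#' Run the SER automaton with scheduled external excitations
#'
#' Like [ser_run()], but at each scheduled `(time, node)` pair the node
#' receives a virtual excited neighbour during the update from `time` to
#' `time + 1`: a susceptible node is excited, excited/refractory nodes are
#' unaffected, and the state is never overwritten in place. Recurrence
#' detection starts after the last scheduled event, so the reported period
#' describes the autonomous tail of the run.
#'
#' @inheritParams ser_run
#' @param schedule a data frame with columns `time` (non-negative, 0-based)
#'   and `node` (1-based node index).
#' @return a `ser_trajectory`.
#' @export
ser_run_perturbed <- function(graph, init, schedule, config = ser_config()) {
  codes <- if (is.character(init)) encode_state(init, config$r) else as.integer(init)
  if (is.null(schedule) || nrow(schedule) == 0)
    return(ser_run(graph, codes, config))
  if (any(schedule$time < 0)) stop("event times must be non-negative")
  if (any(schedule$node < 1 | schedule$node > igraph::vcount(graph)))
    stop("event nodes out of range")
  run_core(propagation_matrix(graph), codes, config$r, config$max_steps,
           events = schedule)
}

#' Random initial condition
#'
#' Each node is independently excited with probability `p_excite`; the
#' remaining nodes are equipartitioned into susceptible and refractory states
#' (ceiling half S, floor half R, assigned at random). Refractory nodes start
#' at the full refractory age.
#'
#' @param n_nodes number of nodes.
#' @param p_excite excitation probability (benchmark value 0.1).
#' @param seed optional integer seed.
#' @return character state vector over `"S"`, `"E"`, `"R"`.
#' @export
random_initial_state <- function(n_nodes, p_excite, seed = NULL) {
  if (p_excite < 0 || p_excite > 1) stop("p_excite must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  labels <- rep("S", n_nodes)
  exc <- runif(n_nodes) < p_excite
  labels[exc] <- "E"
  rest <- which(!exc)
  m <- length(rest)
  if (m > 0) {
    shuffled <- if (m == 1) rest else sample(rest)
    labels[shuffled[seq_len(ceiling(m / 2))]] <- "S"
    if (m > ceiling(m / 2))
      labels[shuffled[seq(ceiling(m / 2) + 1L, m)]] <- "R"
  }
  labels
}

# rows of the periodic orbit (encoded)
orbit_states <- function(traj) {
  traj$states[seq(traj$transient + 1L, traj$transient + traj$period), ,
              drop = FALSE]
}

# state at an arbitrary time, extending the orbit periodically
state_at <- function(traj, t) {
  if (t < nrow(traj$states)) return(traj$states[t + 1L, ])
  off <- (t - traj$transient) %% traj$period
  traj$states[traj$transient + off + 1L, ]
}

#' Mean activity (excitation density) of a trajectory
#'
#' Fraction of nodes in the excited state, averaged over the periodic orbit
#' (the transient is excluded); 0 for extinct runs. A network-wide period-3
#' oscillation gives exactly 1/3, period 4 gives 1/4, and so on.
#'
#' @param traj a `ser_trajectory`.
#' @return a fraction in `[0, 1/ (r+2)]`.
#' @export
mean_activity <- function(traj) {
  if (traj$fate == "extinct") return(0)
  orbit <- orbit_states(traj)
  sum(orbit == 1L) / (nrow(orbit) * ncol(orbit))
}

#' Inter-excitation intervals of a node
#'
#' Gaps between consecutive excitation times of one node over the cyclic
#' orbit (wrap-around included), or an empty vector if the node is never
#' excited in the orbit.
#'
#' @param traj a `ser_trajectory`.
#' @param node 1-based node index.
#' @return integer vector of intervals.
#' @export
node_excitation_intervals <- function(traj, node) {
  orbit <- orbit_states(traj)
  times <- which(orbit[, node] == 1L) - 1L
  if (length(times) == 0) return(integer(0))
  as.integer(diff(c(times, times[1] + nrow(orbit))))
}

#' @export
print.ser_trajectory <- function(x, ...) {
  cat("SER trajectory:", x$n_nodes, "nodes, r =", x$r, "\n")
  cat("  transient:", x$transient, " period:", x$period, " fate:", x$fate, "\n")
  cat("  mean activity:", format(mean_activity(x), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.ser_trajectory <- function(object, ...) {
  list(n_nodes = object$n_nodes, r = object$r, transient = object$transient,
       period = object$period, fate = object$fate,
       mean_activity = mean_activity(object))
}

#' Export a trajectory as TSV plus a JSON summary
#'
#' Writes the recorded states as a T-by-N table of `S`/`E`/`R` labels and,
#' optionally, a JSON summary with transient length, period, fate and mean
#' activity.
#'
#' @param traj a `ser_trajectory`.
#' @param file path of the TSV output.
#' @param summary_file optional path of the JSON summary.
#' @export
write_trajectory <- function(traj, file, summary_file = NULL) {
  lab <- matrix(decode_state(traj$states), nrow = nrow(traj$states))
  utils::write.table(lab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(summary_file)) {
    jsonlite::write_json(summary(traj), summary_file, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(NULL)
}
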