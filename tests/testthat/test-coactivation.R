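test_that("co-activation counts on the triangle pacemaker orbit are exact", {
  tr <- ser_run(triangle_graph(), c("E", "S", "R"))
  c0 <- coactivation_counts(tr, 0)
  # one node excited per step: diagonal 1, off-diagonal 0
  expect_equal(unclass(c0), diag(3), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(c0)))

  # delay +1: each wave-successor pair (i excited right after j) counted once;
  # the wave is E(1) -> E(2) -> E(3) -> E(1)
  c1 <- coactivation_counts(tr, 1)
  expected <- matrix(0, 3, 3)
  expected[2, 1] <- expected[3, 2] <- expected[1, 3] <- 1
  expect_equal(unclass(c1), expected, ignore_attr = TRUE)

  # min-normalization with one excitation per node leaves the counts
  n1 <- normalize_coactivation(c1)
  expect_equal(unclass(n1), expected, ignore_attr = TRUE)
  expect_error(coactivation_counts(ser_run(triangle_graph(), c("E", "S", "S"))),
               "extinct")
})

test_that("phase-aligned disconnected pacemakers co-activate across components", {
  g <- igraph::disjoint_union(triangle_graph(), triangle_graph())
  tr <- ser_run(g, c("E", "S", "R", "E", "S", "R"))
  c0 <- unclass(coactivation_counts(tr, 0))
  expect_equal(c0[1, 4], 1)  # co-phased pair
  expect_equal(c0[2, 5], 1)
  expect_equal(c0[1, 5], 0)  # out of phase
})

test_that("never-excited nodes get zero normalized co-activation", {
  g <- igraph::add_vertices(triangle_graph(), 1)  # isolated fourth node
  tr <- ser_run(g, c("E", "S", "R", "S"))
  n0 <- normalize_coactivation(coactivation_counts(tr, 0))
  expect_equal(unclass(n0)[4, ], rep(0, 4))
  expect_equal(unclass(n0)[, 4], rep(0, 4))
})

test_that("delay +1 counts transpose to the delay -1 matrix", {
  # brute-force oracle on the square orbit: count (i at t+1, j at t) pairs
  tr <- ser_run(square_graph(), c("E", "S", "S", "R"))
  orbit <- sernet:::orbit_states(tr) == 1L
  P <- nrow(orbit)
  oracle_plus <- matrix(0, 4, 4)
  oracle_minus <- matrix(0, 4, 4)
  for (t in seq_len(P)) {
    nxt <- (t %% P) + 1L
    for (i in 1:4) for (j in 1:4) {
      if (orbit[nxt, i] && orbit[t, j]) oracle_plus[i, j] <- oracle_plus[i, j] + 1
      if (orbit[t, i] && orbit[nxt, j]) oracle_minus[i, j] <- oracle_minus[i, j] + 1
    }
  }
  c1 <- unclass(coactivation_counts(tr, 1))
  expect_equal(c1, oracle_plus, ignore_attr = TRUE)
  expect_equal(t(c1), oracle_minus, ignore_attr = TRUE)
})

test_that("adjacent nodes on a unidirectional ring orbit never co-activate", {
  g <- ring_graph(5)
  tr <- ser_run(g, c("E", "S", "S", "S", "R"))
  expect_equal(tr$period, 5)
  n0 <- unclass(normalize_coactivation(coactivation_counts(tr, 0)))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_true(all(n0[A == 1] == 0))
})

test_that("binarization uses strict thresholds and N^2-N density", {
  m <- matrix(0.5, 4, 4)
  b <- binarize(m, 0.46)
  expect_equal(connection_density(b), 1)
  expect_equal(diag(unclass(b)), rep(0, 4))
  expect_equal(connection_density(binarize(m, 0.5)), 0)  # strict inequality
  expect_equal(connection_density(binarize(m, 0.9)), 0)
})

test_that("adjacency correlation is Pearson over off-diagonal entries", {
  g <- generate_er(20, 60, seed = 2)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(adjacency_correlation(A, g), 1)
  comp <- 1 - A
  diag(comp) <- 0
  expect_equal(adjacency_correlation(comp, g), -1)
  expect_true(is.na(adjacency_correlation(matrix(0, 20, 20), g)))
  # independent random binary matrices are uncorrelated
  set.seed(3)
  rs <- replicate(50, {
    m <- matrix(rbinom(400, 1, 0.5), 20, 20)
    diag(m) <- 0
    adjacency_correlation(m, g)
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(20^2 - 20))
})

test_that("the random-sequence baseline matches the closed-form null sd", {
  b <- random_baseline(60, 1000, seed = 5)
  expect_lt(abs(b[["mean"]]), 0.002)
  expect_equal(b[["sd"]], 1 / sqrt(60^2 - 60), tolerance = 0.1)
  expect_identical(random_baseline(60, 100, seed = 9),
                   random_baseline(60, 100, seed = 9))
  expect_error(random_baseline(60, 1), "n_sequences")
})

test_that("threshold sweeps have monotone density and sane endpoints", {
  g <- generate_er(30, 120, seed = 4)
  avg <- average_coactivation(g, n_init = 50, delay = 0, seed = 6)
  expect_true(isSymmetric(unclass(avg)))
  expect_true(all(unclass(avg) >= 0 & unclass(avg) <= 1))
  curve <- threshold_sweep(avg, g, n_baseline = 100, seed = 6)
  expect_true(all(diff(curve$density) <= 1e-12))
  expect_equal(curve$density[curve$threshold == 1], 0)
  expect_true(all(curve$density >= 0 & curve$density <= 1))
})

test_that("averaging requires at least one sustained run and honors n_init = 1", {
  # a single edge cannot sustain activity (no cycle of length >= 3)
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  expect_error(average_coactivation(g2, n_init = 20, seed = 1), "sustained")

  g <- generate_er(30, 150, seed = 8)
  avg1 <- average_coactivation(g, n_init = 1, delay = 0, seed = 12)
  # reproduce the single run by hand with the same RNG stream
  set.seed(12)
  init <- random_initial_state(30, 0.1)
  tr <- ser_run(g, init)
  expect_equal(unclass(avg1),
               unclass(normalize_coactivation(coactivation_counts(tr, 0))),
               ignore_attr = TRUE)
  expect_equal(attr(avg1, "n_runs"), 1L)
})
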