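test_that("the synchronous update follows the three SER rules", {
  tri <- triangle_graph()
  expect_equal(ser_step(tri, c("E", "S", "R")), c("R", "E", "S"))
  # both neighbours of the middle node get excited on a path
  expect_equal(ser_step(path3_graph(), c("S", "E", "S")), c("E", "R", "E"))
  # without excitations (and no external input) no excitation can appear
  for (i in 1:20) {
    g <- random_test_graph(8, 0.4)
    st <- sample(c("S", "R"), 8, replace = TRUE)
    expect_false("E" %in% ser_step(g, st))
  }
  # external input acts as a virtual excited neighbour on S nodes only
  expect_equal(ser_step(tri, c("S", "S", "S"), external = 2L), c("S", "E", "S"))
  expect_equal(ser_step(tri, c("R", "R", "R"), external = 2L), c("S", "S", "S"))
})

test_that("recurrence detection splits trajectories into transient and orbit", {
  tri <- triangle_graph()
  t1 <- ser_run(tri, c("E", "S", "R"))
  expect_equal(t1$transient, 0)
  expect_equal(t1$period, 3)
  expect_equal(t1$fate, "sustained")

  # E,S,S dies: ESS -> REE -> SRR -> SSS (fixed point)
  t2 <- ser_run(tri, c("E", "S", "S"))
  expect_equal(t2$fate, "extinct")
  expect_equal(t2$transient, 3)
  expect_equal(t2$period, 1)
  lab <- apply(t2$states, 1, function(s) paste(c("S", "E", "R")[pmin(s, 2) + 1], collapse = ""))
  expect_equal(lab, c("ESS", "REE", "SRR", "SSS"))

  t3 <- ser_run(square_graph(), c("E", "S", "S", "R"))
  expect_equal(t3$period, 4)
  expect_equal(t3$fate, "sustained")

  # the cap raises when no recurrence is found in time
  expect_error(ser_run(square_graph(), c("E", "S", "S", "R"), ser_config(max_steps = 2)),
               "max_steps")
})

test_that("mean activity and inter-excitation intervals match the canonical orbits", {
  tri <- ser_run(triangle_graph(), c("E", "S", "R"))
  expect_identical(mean_activity(tri), 1 / 3)
  for (v in 1:3) expect_equal(node_excitation_intervals(tri, v), 3)

  sq <- ser_run(square_graph(), c("E", "S", "S", "R"))
  expect_identical(mean_activity(sq), 1 / 4)
  for (v in 1:4) expect_equal(node_excitation_intervals(sq, v), 4)

  dead <- ser_run(triangle_graph(), c("E", "S", "S"))
  expect_identical(mean_activity(dead), 0)
  expect_length(node_excitation_intervals(dead, 1), 0)
})

test_that("scheduled excitations act as virtual neighbours and can slip the phase", {
  sq <- square_graph()
  init <- c("E", "S", "S", "R")
  # excite the S two steps ahead of the wave: the wave jumps forward and the
  # initial configuration recurs after 3 instead of 4 steps
  tp <- ser_run_perturbed(sq, init, data.frame(time = 0L, node = 3L))
  expect_equal(tp$states[2, ], c(2L, 1L, 1L, 0L))  # R,E,E,S
  expect_equal(tp$states[4, ], sernet:::encode_state(init))  # recurs at t = 3
  expect_equal(tp$fate, "sustained")

  # the triangle pacemaker is immune: E/R nodes ignore input and the single S
  # node is excited at the next step regardless
  tri <- triangle_graph()
  base <- ser_run(tri, c("E", "S", "R"))
  sched <- data.frame(time = c(0L, 1L, 2L, 5L), node = c(1L, 2L, 3L, 2L))
  pert <- ser_run_perturbed(tri, c("E", "S", "R"), sched)
  for (t in 0:(nrow(pert$states) - 1)) {
    expect_equal(pert$states[t + 1, ], sernet:::state_at(base, t))
  }

  # empty schedule reduces to the autonomous run
  t0 <- ser_run_perturbed(sq, init, data.frame(time = integer(0), node = integer(0)))
  expect_identical(t0$states, ser_run(sq, init)$states)
})

test_that("random initial conditions have the E rate and exact S/R equipartition", {
  expect_equal(sort(table(random_initial_state(10, 0, seed = 1))),
               sort(table(c(rep("S", 5), rep("R", 5)))))
  expect_equal(random_initial_state(10, 1, seed = 1), rep("E", 10))

  set.seed(42)
  for (i in 1:25) {
    st <- random_initial_state(60, 0.1)
    m <- sum(st != "E")
    expect_equal(sum(st == "S"), ceiling(m / 2))
    expect_equal(sum(st == "R"), floor(m / 2))
  }
  # excitation rate is Binomial(n, 0.1)
  set.seed(7)
  ne <- mean(replicate(200, sum(random_initial_state(60, 0.1) == "E")))
  expect_lt(abs(ne - 6), 1)
})

test_that("determinism and automorphism equivariance hold", {
  g <- random_test_graph(12, 0.3)
  init <- random_initial_state(12, 0.2, seed = 3)
  expect_identical(ser_run(g, init)$states, ser_run(g, init)$states)

  # relabelling nodes commutes with the update
  set.seed(11)
  for (i in 1:10) {
    g <- random_test_graph(10, 0.3)
    perm <- sample(10)
    g2 <- igraph::permute(g, perm)
    st <- sample(c("S", "E", "R"), 10, replace = TRUE)
    st2 <- character(10)
    st2[perm] <- st
    out2 <- ser_step(g2, st2)
    out <- ser_step(g, st)
    expect_equal(out2[perm], out)
  }
})

test_that("the all-S state is the only fixed point", {
  set.seed(13)
  for (i in 1:30) {
    g <- random_test_graph(8, 0.4)
    st <- sample(c("S", "E", "R"), 8, replace = TRUE)
    if (all(st == "S")) st[1] <- "E"
    expect_false(identical(ser_step(g, st), st))
  }
  g <- random_test_graph(8, 0.4)
  expect_identical(ser_step(g, rep("S", 8)), rep("S", 8))
})

test_that("dense random graphs predominantly lock to period 3 at activity 1/3", {
  g <- generate_er(60, 800, seed = 21)
  set.seed(22)
  periods <- integer(0)
  acts <- numeric(0)
  for (i in 1:30) {
    tr <- ser_run(g, random_initial_state(60, 0.1))
    if (tr$fate == "sustained") {
      periods <- c(periods, tr$period)
      acts <- c(acts, mean_activity(tr))
    }
  }
  expect_gt(length(periods), 20)
  expect_equal(as.integer(names(which.max(table(periods)))), 3)
  expect_equal(as.numeric(names(which.max(table(acts)))), 1 / 3, tolerance = 1e-9)
})

test_that("activity is bounded by 1/(r+2) globally and per node", {
  set.seed(17)
  for (i in 1:40) {
    g <- random_test_graph(sample(6:15, 1), runif(1, 0.15, 0.5))
    n <- igraph::vcount(g)
    tr <- ser_run(g, random_initial_state(n, runif(1, 0.05, 0.4)))
    expect_lte(mean_activity(tr), 1 / 3 + 1e-12)
    if (tr$fate == "sustained") {
      orbit <- sernet:::orbit_states(tr)
      freq <- colSums(orbit == 1L) / nrow(orbit)
      expect_true(all(freq <= 1 / 3 + 1e-12))
    }
  }
})

test_that("trajectories export as label tables with a JSON summary", {
  dir <- withr::local_tempdir()
  tr <- ser_run(triangle_graph(), c("E", "S", "R"))
  f <- file.path(dir, "traj.tsv")
  j <- file.path(dir, "traj.json")
  write_trajectory(tr, f, j)
  tab <- read.delim(f, header = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(unname(unlist(tab[1, ])), c("E", "S", "R"))
  s <- jsonlite::read_json(j)
  expect_equal(s$period, 3)
  expect_equal(s$fate, "sustained")
})
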