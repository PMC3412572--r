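# sernet

Deterministic excitable SER dynamics on networks.

`sernet` simulates and exhaustively analyses the minimal deterministic
three-state excitable cellular automaton on graphs, a toy model of neuronal
tissue used to study how network topology shapes self-sustained activity and
functional connectivity. Each node is **S**usceptible, **E**xcited or
**R**efractory, and all nodes update synchronously:

* S → E when at least one direct neighbour is excited,
* E → R always,
* R → S after *r* time steps (the refractory period; the analyses here use
  *r* = 1).

Because the dynamics are deterministic and the state space is finite, every
run ends in a periodic orbit — either the all-S fixed point (extinction) or a
cycle of states containing excitations (sustained activity). The package is
aimed at researchers in network/computational neuroscience who want the full,
exact picture that this stylised model affords: complete basins of
attraction for small motifs, exact cycle censuses, and reproducible
structure–function comparisons.

## What the package computes

* **Benchmark graphs** (`generate_er`, `generate_ba`, `generate_modular`):
  Erdős–Rényi G(N, M), Barabási–Albert preferential attachment (exactly
  (N−m)·m edges), and compositions of ER modules with few inter-module
  links; plus plain-text graph IO (`read_network` / `write_network`:
  edge list, 0/1 adjacency, GraphML) so that empirical connectomes can be
  supplied as files.
* **Dynamics** (`ser_run`, `ser_run_perturbed`): synchronous updates with
  exact recurrence detection (transient length, orbit period, fate), random
  initial conditions (excitation probability *p*, S/R equipartition), mean
  activity ⟨fraction of excited nodes⟩ over the orbit, per-node
  inter-excitation intervals, and scheduled external excitations that act as
  virtual excited neighbours.
* **Functional connectivity** (`coactivation_counts`,
  `average_coactivation`, `threshold_sweep`): co-activation matrices at
  delay 0 and +1, min-normalised (count divided by the smaller of the two
  nodes' excitation counts), averaged over many initial conditions,
  thresholded into binary functional networks, and correlated (Pearson,
  off-diagonal entries) with the structural adjacency matrix against a
  random-sequence baseline.
* **Cycle counting** (`count_elementary_cycles`, `brute_force_census`):
  exact oriented elementary-cycle counts C(n) = Tr B⁽ⁿ⁾ / n from an
  end-constrained recursion over loop-free path-count matrices with
  excluded-node bookkeeping, an independent depth-first oracle, and the
  factor-2 orientation correction for undirected graphs.
* **Motif atlas** (`enumerate_fates`, `basin_invariance_check`,
  `phase_slip_scan`): exhaustive 3ᵏ fate enumeration for small cyclic
  devices (triangles, squares) and their pendant embeddings, rotation
  reduction of initial conditions, the ESR-pacemaker basin-invariance
  check, and phase-slip scans under single external excitations.
* **Experiment drivers** (`exp_threshold_sweep`, `exp_hub_removal`,
  `exp_activity_vs_cycles`) and a thin command-line front end in
  `inst/cli/sernet.R` with subcommands `generate`, `simulate`,
  `coactivation`, `cycles`, `motifs`, `experiment`.

## Worked example

```r
library(sernet)

# the triangle pacemaker: ESR cycles forever with period 3
tri <- igraph::make_ring(3)
traj <- ser_run(tri, c("E", "S", "R"))
traj
#> SER trajectory: 3 nodes, r = 1
#>   transient: 0  period: 3  fate: sustained
#>   mean activity: 0.3333
node_excitation_intervals(traj, 1)
#> [1] 3
```

Every node fires every 3 steps, so the excitation density is exactly 1/3.
Exhaustive enumeration shows this is the *only* way a triangle sustains
activity — of its 27 initial conditions, just the two wave orientations
(ESR and ERS, three rotations each) survive:

```r
red <- reduce_by_rotation(enumerate_fates(device_spec(3)))
red[red$fate == "sustained", ]
#>  representative class_size      fate period
#>             ERS          3 sustained      3
#>             ESR          3 sustained      3
```

On a scale-free graph, functional connectivity *anti*-correlates with
structure: hubs excite their many neighbours simultaneously, while linked
node pairs, which hand excitation to each other, can never fire together:

```r
g <- generate_ba(60, 800, seed = 1)          # 60 nodes, 800 links, m = 20
avg <- average_coactivation(g, n_init = 500, delay = 0, seed = 1)
avg
#> Co-activation matrix: 60 nodes, delay 0 (normalized)
#>   averaged over 500 sustained run(s)
curve <- threshold_sweep(avg, g, seed = 1)
curve[which.min(abs(curve$density - 0.5)), ]
#>  threshold   density correlation baseline_mean baseline_sd
#>       0.42 0.4271186  -0.1278139   0.001076975   0.0164395
```

At the threshold where the binarised co-activation matrix has connection
density ≈ 0.5, the correlation with the adjacency matrix is −0.128 — far
below the random-sequence baseline (mean ≈ 0.001, sd ≈ 0.016), i.e., a
clear structure–function anti-correlation. The same pipeline on
`generate_modular(60, 800, 4, seed = 1)` flips the correlation positive:
modular organisation overrides the anti-correlation.

The exact cycle census of the same graph (oriented counts and their
undirected halves):

```r
undirected_correction(count_elementary_cycles(g, 4))
#> Elementary cycle census (undirected graph):
#>   C(3) = 8450  [4225 undirected]
#>   C(4) = 181964  [90982 undirected]
```

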