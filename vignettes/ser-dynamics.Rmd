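---
title: "Excitable SER dynamics on networks: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitable SER dynamics on networks: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sernet)
```

## The model

Each node of a graph carries one of three states: susceptible (S), excited
(E) or refractory (R). All nodes update synchronously in discrete time:

1. S → E when at least one direct neighbour is excited (on directed graphs,
   an in-neighbour: excitation flows along edge direction);
2. E → R unconditionally;
3. R → S after `r` time steps.

The refractory period `r` (default 1, the value used throughout the
benchmark analyses) is the model's only dynamical parameter. The automaton
is deterministic, so on a finite graph every trajectory eventually revisits
a state and from then on repeats: the trajectory splits into a transient
prefix and a periodic orbit. The all-S state is the only fixed point (an E
always becomes R, an R always ages), so a run either goes *extinct* (its
orbit is the all-S point) or is *sustained* (its orbit contains
excitations). `ser_run()` detects the recurrence exactly, by memoizing each
full network state until one repeats; memory grows only with the actual
transient-plus-period length. The search is capped at `max_steps` (default
30,000, configurable via `ser_config()`); the cap exists because the state
space, though finite, is size 3^N — in practice 60-node benchmark runs
recur within tens of steps.

Because a node needs at least `r + 2` steps between consecutive
excitations (E, then R for `r` steps, then S for at least one step before
it can fire), per-node excitation frequency is bounded by 1/(r+2), and so
is the orbit-averaged excitation density. For `r = 1` this is the 1/3
ceiling that dense networks actually attain: the typical collective state
is a period-3 oscillation in which the nodes partition into three groups
firing in rotation.

## Initial conditions

`random_initial_state()` implements the benchmark protocol: each node is
independently excited with probability `p_excite` (default 0.1) and the
remaining nodes are equipartitioned — exactly ⌈half⌉ S and ⌊half⌋ R,
assigned at random. Initially refractory nodes start at the full
refractory age; for `r = 1` the age plays no role. Averaged quantities use
500 initial conditions by default (`experiment_config()`), with extinct
runs excluded from co-activation averages since functional connectivity is
defined on sustained activity.

## External excitations

A scheduled perturbation `(t, node)` in `ser_run_perturbed()` acts as a
*virtual excited neighbour* during the update from `t` to `t+1`: a
susceptible node fires, excited and refractory nodes are untouched, and no
state is ever overwritten in place. The design was chosen over
overwrite-to-E semantics because overwriting would destroy the triangle
pacemaker (rewriting its S node to E mid-cycle kills the wave), whereas the
established result — and this package's exhaustive scans — show the
pacemaker is immune to arbitrary external input: its E and R nodes cannot
receive input, and its S node fires at the next step regardless. With
virtual-neighbour semantics the square device reproduces the full
phenomenology of phase slips: an excitation landing on the susceptible node
two steps ahead of the wave advances the wave, shortening the recurrence of
the initial configuration from 4 to 3 steps (`phase_slip_scan()` scans all
single events). Recurrence detection in perturbed runs starts only after
the last scheduled event, so reported periods always describe the
autonomous tail.

## Co-activation analysis

`coactivation_counts()` accumulates, for every ordered node pair, joint
excitations over exactly one periodic orbit, cyclically. The orbit — not a
fixed observation window — is the package's choice of measurement unit:
the dynamics are exactly periodic after the transient, so any
window-based count is the orbit count times a window factor plus edge
effects, and the orbit makes the statistic exact and parameter-free. Delay
0 counts simultaneous excitations; delay +1 counts node *i* firing one step
after node *j* (the −1 matrix is the transpose). Counts are min-normalised
(divided by the smaller of the two nodes' per-orbit excitation counts, 0
if a node never fires) and averaged over sustained runs.

The averaged matrix is thresholded *strictly* (entry 1 iff value > θ),
the diagonal is excluded everywhere, and connection density is ones /
(N² − N). `threshold_sweep()` records density and the Pearson correlation
between the flattened off-diagonal binary matrix and the adjacency matrix
over a grid (default 0 to 1, step 0.02). A zero-variance flattened
sequence (all-ones or all-zeros at extreme thresholds) yields an `NA`
correlation rather than an error so sweeps never abort. The baseline is
the mean ± sd correlation of `n_baseline = 1000` pairs of independent
equiprobable binary sequences of the same length; correlating two random
sequences (rather than a random sequence against the adjacency matrix) was
chosen as the more symmetric null — both variants have mean ≈ 0 and sd ≈
(N² − N)^(−1/2) ≈ 0.017 for N = 60, so the choice does not affect any
conclusion.

On scale-free graphs the sweep shows the characteristic structure–function
*anti*-correlation at intermediate densities: hubs co-activate their many
neighbours while directly linked pairs, which pass excitation to one
another, can never fire simultaneously (on a single unidirectional ring
orbit the delay-0 co-activation of adjacent nodes is exactly zero). On
modular graphs the within-module coherence overrides this effect and the
correlation turns positive. `exp_hub_removal()` interpolates between the
two regimes by deleting hubs one at a time (highest current degree first,
degrees recomputed between deletions).

## Benchmark graphs

* `generate_er(n, m, seed)` draws G(N, M) uniformly (via igraph), giving
  exactly `m` edges.
* `generate_ba(n, m_links, seed)` uses preferential attachment with an
  integer attachment parameter m chosen so the final count (N − m)·m best
  matches the requested links (60 nodes / 800 links ⇒ m = 20, exact); the
  generator starts from m isolated seed nodes and attaches each newcomer
  to m distinct degree-weighted targets. It errors if no m comes within 5%.
* `generate_modular(n, m, k, inter, seed)` composes k equal ER blocks with
  `m − inter` intra-module edges split evenly and `inter` cross-module
  edges (default 5% of m, as "few links among them" is not a number).
  One numerical subtlety is handled explicitly: the 60-node / 800-link /
  4-module benchmark requests 190 intra edges per 15-node module, but a
  15-node simple module holds at most 105. The generator therefore fills
  modules to capacity and spills the overflow into the inter-module pool,
  keeping the total edge count exact; the parameter error is reserved for
  requests beyond total graph capacity. The resulting benchmark — complete
  modules plus ~380 cross links — is the only simple-graph realisation of
  those parameters, and it does reproduce the positive structure–function
  correlation expected of modular organisation.

All generators are deterministic given `seed`. Node ids are 1-based in the
R API; the edge-list file dialect uses 0-based ids (converted on
read/write), `#` comments, and one line per undirected edge.

## Cycle counting

`count_elementary_cycles()` implements the exact trace recursion
C(n) = Tr B⁽ⁿ⁾ / n, where B⁽ⁿ⁾ counts n-step paths with pairwise-distinct
interior nodes. B⁽¹⁾ = A and B⁽²⁾ = A²; from n = 4 on, loop-freedom
requires auxiliary matrices D⁽q | a₁..a_z⁾ of q-step path counts avoiding
an excluded node set, built by a recursion that adds the path's endpoint to
the exclusion set of the sub-problem. The implementation memoizes the D
family keyed by (q, sorted exclusion set), materialising exclusion sets
lazily. The maximum cycle length is capped at 7: the recursion bottoms out
in all D⁽² | a₁..a_{n−3}⁾ matrices, whose number grows combinatorially
with n, and the analyses in this package need only n = 3, 4. The diagonal
of B⁽²⁾ (equal to the degrees) is never consumed by the trace steps since
every closing step multiplies by A_ki and A_ii = 0.

Counts are oriented: on undirected graphs each elementary cycle is counted
once per traversal direction for *every* n ≥ 3 — including n = 3, where
Tr(A³)/3 on the single triangle K3 gives 2 — so `undirected_correction()`
halves all counts uniformly, enforcing the evenness invariant first. The
independent oracle `brute_force_census()` (depth-first enumeration with
canonical minimum-start deduplication) confirms both the counts and the
factor 2 on random directed and undirected graphs; the test suite pins the
two routes against each other exactly.

## Motif atlas

`enumerate_fates()` simulates all 3ᵏ initial conditions of a device (a
ring plus optional pendant attachments from `device_spec()`; capped at
k = 12 nodes) and tabulates fate, period and transient, with sustained
counts stratified by the number of initial excitations.
`reduce_by_rotation()` groups initial conditions under cyclic rotations
only — not reflections, because the two wave orientations ESR and ERS are
physically distinct orbits and full dihedral reduction would merge them.
For the triangle this yields exactly two sustained classes.

`basin_invariance_check()` tests the pacemaker-basin claim exhaustively:
for every initial condition of an embedded device, the observed fate is
compared with the predictor "the cycle sub-state is one of the isolated
cycle's sustained configurations". For all pendant embeddings of the
triangle with 5–7 nodes the agreement is exactly 100% — the embedding
changes the basin of attraction not at all, only combinatorially through
the pendant states. For the square the check reports the agreement
fraction and the complete counterexample list rather than assuming
robustness; squares, unlike triangles, can be re-phased by incoming
excitations, which is also why they exhibit phase slips.

Pendant attachments (trees hanging off cycle nodes) are the default
embedding family; arbitrary surroundings can be analysed by passing any
igraph whose first L nodes are the cycle.

## Problem sizes and test design

The package's statistical checks run at the benchmark scale chosen for the
analyses: 60-node graphs, 500 initial conditions for co-activation
averages, 1000 baseline sequence pairs, 50-graph ensembles with 100
initial conditions per graph for the activity-versus-cycles experiment,
and 50 random graphs (N ≤ 10, both orientations, densities 0.1–0.6) for
the recursion-versus-oracle cross-check. These sizes give sub-minute
runtimes while leaving the statistical conclusions far from their decision
boundaries (e.g., the measured anti-correlation is ≈ −0.13 against a null
sd of ≈ 0.017).

One empirical regime boundary deserves note. Mean activity correlates
positively with the number of 3-cycles only where graphs are sparse enough
that sustained runs do *not* all lock to the period-3 ceiling: at 60
nodes / 100 links (mean degree 3.3) activities spread over 1/3, 1/4, 1/5
and the ensemble correlation with C(3) is strong and robust, while at 60
nodes / 250 links (mean degree 8.3, ~96 triangles) essentially every
sustained run already attains density 1/3, leaving no variance for a
topological signal. The test suite demonstrates the correlation in the
sparse regime and also runs the denser ensemble for comparison.

## What the generators do and do not emulate

The synthetic benchmarks reproduce the *topological* features whose
dynamical consequences the package measures: uniform randomness (ER),
hubs (BA), and modular blocks. They are simple, unweighted, and —
except for optional file input — undirected; they do not emulate weighted
or distance-dependent connectivity, degree correlations, or the
community-size heterogeneity of real connectomes. Passing tests therefore
certify the mechanisms (pacemakers, anti-correlation, sign flip under
modularity, hub-removal interpolation), not quantitative agreement with
any particular empirical brain network; empirical matrices can be supplied
via `read_network()` and run through the identical pipeline.

## Known limitations

* The deterministic model has no spontaneous excitation or probabilistic
  recovery; it is the limiting case of the stochastic three-state family,
  and stochastic variants are out of scope.
* Exhaustive enumeration is exponential (3ᵏ) and capped at 12-node
  devices; cycle counting is capped at length 7.
* Synchronous update only; asynchronous schedules change the model class.
* `average_coactivation()` excludes extinct runs; on graphs that cannot
  sustain activity at all it raises an error rather than returning an
  empty average.
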