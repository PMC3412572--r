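Package: sernet
Title: Deterministic Excitable SER Dynamics on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and exhaustive analysis of the deterministic
    three-state excitable cellular automaton (susceptible-excited-refractory)
    on graphs. Provides benchmark graph generators (Erdos-Renyi,
    Barabasi-Albert, random-modular) and plain-text graph IO; synchronous
    SER dynamics with exact recurrence (transient/period/fate) detection and
    perturbed runs; co-activation (functional-connectivity) matrices with
    min-normalization, thresholding and structure-function correlation
    analysis; exact elementary-cycle counting by an end-constrained matrix
    recursion with a brute-force oracle; exhaustive basin-of-attraction
    enumeration for small cyclic motifs and their embeddings, including
    pacemaker robustness and phase-slip scans; and drivers for composite
    threshold-sweep, hub-removal and activity-versus-cycles experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
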