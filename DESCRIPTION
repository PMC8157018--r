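Package: evacsim
Title: Agent-Based Crowd Evacuation Simulation on a Floor-Field Grid
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Microscopic agent-based simulation of crowd evacuation from a
    bounded two-dimensional cellular grid with two exits. A floor field
    (per-exit hop counts and best directions, spread outward from the exits
    through Moore neighborhoods) guides movement; evacuees follow a
    WALK/WAIT/PANIC state machine with a mobility index, and choose between
    exits by one of four strategies: nearest exit, local social influence
    with game-theoretic switching, technological influence through an
    agent-borne decaying exit-potential field, and small-world social
    influence through long-distance ties. Includes deterministic seeded
    runs, batch experiment sweeps with paired replicates, CSV output, and
    generators for preset and synthetic test environments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
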