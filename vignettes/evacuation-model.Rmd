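---
title: "The evacuation model behind evacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evacuation model behind evacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacsim)
```

evacsim simulates the egress of a crowd from a bounded two-dimensional
cellular grid with two exits, labelled *left* and *right*. This vignette
explains the model the package implements, the parameters that matter, the
numerical conventions, and — importantly — what the synthetic environments
and the scaled-down test runs can and cannot say about real evacuations.

## Space: the grid and the floor field

The world is a bounded lattice of square patches (the standard room is
51 × 51, i.e. 2,601 cells), each of which is *normal* (walkable floor), an
*obstacle*, or an *exit* patch. Exit patches are walkable; an agent that
steps onto one leaves the simulation immediately. There is no wrap-around
and at most one agent occupies a patch at any instant.

Navigation uses a *floor field*: for each exit label, every patch carries
`hops` — the minimal number of cell-to-cell steps to any patch of that
exit, counted over the Moore (8-cell) neighborhood and never passing
through obstacles — and `doms`, the compass direction towards the neighbor
through which that minimum is achieved. The spread starts at the exit
patches (distance 0) and disperses outward; a cell adopts a neighbor's
information whenever it implies a smaller hop count. Exit and obstacle
patches themselves keep the `-1` sentinel in both fields, as do walkable
patches in sealed pockets.

Conventions that had to be fixed and are therefore part of the package's
contract:

* **Directions** are compass degrees in {0, 45, …, 315}, 0 = north (up,
  towards larger `y`), clockwise. A cell whose best information arrives
  from its south-east neighbor points 135°.
* **Coordinates** are 0-based, `x` = column, `y` = row, origin at the
  bottom-left; map files list the top row first.
* **Tie-break**: when two neighbors offer the same minimal hop count,
  `doms` takes the first in the fixed scan order N, NE, E, SE, S, SW, W,
  NW. This makes the field a pure function of the map.

Hop counts are unweighted: a diagonal step costs the same as an orthogonal
one, so `hops` equals the Chebyshev distance in an open room. The
floor-field implementation is a multi-source breadth-first search; the
test suite checks it cell-for-cell against an independent shortest-path
oracle (igraph) on randomized obstacle maps.

One geometric subtlety: a shortest path towards one exit may pass through
a patch of the *other* exit (exit patches are walkable). An agent
following such a path is simply absorbed by the exit it steps onto first,
which is the behaviorally sensible outcome; the greedy-descent test
accounts for it.

## Agents: WALK, WAIT, PANIC and the Mobility Index

Evacuees are *emotional* or *rational*. Each tick an agent, in a freshly
randomized activation order, (1) decides which exit to head for, (2) sets
its heading from the floor field of that exit, (3) tries to move, and
(4) updates its cognitive state, its three indices and its Mobility
Index.

Movement is microscopic — at most one cell per tick. The agent scans its
eight neighbors in a dial around the heading, at angular offsets 0°, +45°,
−45°, +90°, −90°, +135°, −135°, 180° (positive = clockwise), and takes the
first in-bounds, walkable, unoccupied cell. Occupancy is claimed
atomically in activation order, so two agents never move into the same
cell in one tick. The exact dial numbering is only shown graphically in
the source material; the alternating nearest-angle-first order used here
is symmetric and configurable in spirit (it lives in one table in the
engine).

The cognitive state machine: an agent that moved is in WALK; one that
failed to move is in WAIT while its waiting index is below the panic
threshold and in PANIC otherwise. Exactly one of the three indices
(moving, waiting, panic) is incremented each tick according to the new
state while the other two are reset to 0. Two consequences of reading
this rule literally are worth spelling out:

* the panic threshold is measured in consecutive blocked ticks, and
* because entering PANIC resets the waiting index, a *persistently*
  blocked agent cycles WAIT × threshold → PANIC → WAIT × threshold → … .
  The `ever_panicked` reporters latch the first PANIC entry, so they are
  unaffected by the cycling; the "maximum concurrently panicking"
  reporter counts the PANIC phase of the cycle only.

The threshold itself is not stated in the source material; the package
default is 4 ticks and it is an explicit `sim_config()` parameter.

The **Mobility Index** (MI) summarizes recent movement quality: +1 per
WALK tick, −1 per WAIT tick, and under PANIC it contracts towards zero,
`MI ← MI − MI × sensitivity`, with the standard sensitivity of 0.5 (so a
panicking agent's MI halves each tick). MI is deliberately unclamped —
it may go negative — because strategy S4 compares MI values across agents
and clamping would silently reorder them.

## The four exit-choice strategies

* **S1 (individual)**: every agent keeps the nearest exit fixed at
  initialization. The baseline.
* **S2 (local social)**: each tick the agent samples one random occupant
  of its Moore neighborhood. A calm rational agent whose neighbor shares
  its exit switches away with probability 0.1 (random deviation); one
  whose neighbor disagrees switches with probability 0.9. A *panicking*
  rational agent does the opposite of herding: if the neighbor shares its
  exit it switches with certainty, and if the neighbor disagrees it holds
  course. Emotional agents mimic: only when panicking do they adopt a
  disagreeing neighbor's exit, with probability 0.1.
* **S3 (technological)**: rational agents only; emotional agents keep the
  nearest exit with no deviation. On top of the sampled neighbor, the
  agent reads the *dominant exit* of its patch — the exit whose potential
  value (below) is strictly larger. The switch probability combines
  panic (weight 0.5) with negative social and technological inputs
  (0.25 each): 0/0.25/0.25/0.50 for the calm branches and
  0.50/0.75/0.75/1.00 for the panic branches, following the published
  decision table. (The two panic branches where the neighbor disagrees
  carry 1.00 when the potential confirms the current exit and 0.75 when
  it contradicts it — the published pseudocode and its prose agree on
  this, although a strict additive weight reading would swap them; the
  package follows the pseudocode.)
* **S4 (small-world social)**: as S2, except that every rational agent
  owns one static long-distance tie to a uniformly chosen other agent,
  and a panicking rational agent adopts the exit of its most mobile
  contact — the argmax of MI over Moore occupants plus the distant tie
  (ties broken uniformly). A tie whose endpoint has already exited is
  inert. If no contact exists the agent keeps its exit.

Absent influence channels never force a choice: no neighbor, no dominant
potential, or no contact all mean "keep the current exit". In particular
S3 agents behave like S1 until the first exit event creates potential.
All branch probabilities are exposed in `decision_probs()` for
sensitivity analysis; the defaults are the published values.

## The exit-potential layer (S3)

When an agent leaves through an exit, all Moore neighbors of that exit
patch get potential value 1 for that exit's field. The announcement then
spreads *through agents*, not through the environment: each tick, every
occupied patch P with positive potential passes `0.9 × pv(P)` to any
Moore neighbor currently holding less (taken as a max, synchronously from
a snapshot, so the result does not depend on agent order). Finally both
fields decay multiplicatively, by a factor 0.99 per tick by default, with
values below 10⁻⁶ snapped to zero. Decay runs last in the tick and also
touches freshly seeded values.

Two readings of the attenuation sentence in the source material are
possible; the package passes on nine tenths of the source value rather
than subtracting a tenth of it from the receiver, because the
subtractive reading can drive values negative and contradicts the stated
picture of announcements spreading "with lesser and lesser intensity".
The decay rate is not stated at all; 0.99 keeps information useful for a
couple of hundred ticks — the time scale of a 51 × 51 crossing — and is a
`sim_config()` parameter, not a constant.

## The tick loop and reproducibility

Per tick: agents are activated in a fresh uniform-random permutation;
each activated agent runs decide → adjust heading → select cell → move and
update state → update MI; an agent reaching an exit patch is removed at
that instant (its cell frees immediately, so a queue can drain several
agents through one exit cell in a single tick, exactly as sequential
activation implies); after all activations, under S3, the potential
spreads and decays. The simulation stops when the world is empty or at
`max_ticks` (default `50 × (width + height)`), in which case the result
is flagged non-terminated — the designed behavior for maps with sealed
pockets.

A single RNG stream drives everything — placement, typing, ties,
activation order, every Bernoulli draw — so a `(config, seed)` pair
reproduces a run bit for bit, on any machine. Sweeps derive replicate
seeds as `base_seed + replicate − 1`, which deliberately reuses identical
initial placements across strategies and percentages: comparisons between
cells are paired by seed, which sharpens small-sample ordering tests.

## Environments, presets and fixtures

The presets E1–E4 approximate the published geometries: a square room
with a 3-patch exit centered on each of the west and east walls (the
source figures show multi-patch exits but never state a width). E1 is
open; E2–E4 place a vertical obstacle wall three columns in front of the
right exit, centered, with length `round(f · (size − 2))` rounded to odd
for f = 0.30, 0.55, 0.80, clamped to keep the wall ends open. The exact
wall shapes are only shown graphically in the source; this construction
preserves the one property the text states — the fraction of walkable
patches nearer the left exit increases strictly from E1 to E4 — which the
test suite verifies by hop counts rather than by trusting the drawing.

`generate_fixture_world()` provides the synthetic test geometries: `open`
(no obstacles), `corridor` (a single-cell passage, which serializes
movement), `pocket` (a sealed unreachable region, for the non-termination
path), and `asymmetric` (an E3-like partial wall, single-cell exits).
These are *test stand-ins*, not reproductions of any published floor
plan.

## What the scaled-down experiments do and do not show

The full published design — 4 environments × 4 strategies × 4 rational
percentages × 50 replicates at 1,000 agents — runs in minutes with this
engine (`run_sweep()` with the defaults). The test suite, however, keeps
its stochastic reproduction at a reduced scale: a 21 × 21 asymmetric
world, 200 agents, 15% rational, 10 paired replicates, with one-sided
paired Wilcoxon tests at α = 0.05 for the strategy orderings (social
strategies panic less and balance exits better; the nearest-exit strategy
evacuates faster).

Scale matters for one of these phenomena. Panic requires an agent to fail
to move for more than `panic_threshold` consecutive ticks, which in turn
requires a jam deep enough that its interior stays fully enclosed while
holes cascade inward from departures. At 200 agents on a 21 × 21 grid the
jam drains in roughly 45 ticks and blocked streaks barely reach the
default threshold of 4, so almost nobody panics — and an ordering between
near-zero panic counts is statistically undetectable at 10 replicates. At
the full scale of 1,000 agents on 51 × 51 the same engine produces
substantial panic (hundreds of agents enter PANIC at least once) and the
published orderings appear directionally. The reduced-scale exit-time and
exit-usage orderings do reproduce. This is stated here so that a failing
reduced-scale panic ordering is read for what it is: a property of the
model at that problem size, not a defect of the implementation — and,
conversely, so that passing tests are not over-read: the synthetic
worlds lack smoke, visibility limits, heterogeneous speeds and real
building topology, and say nothing about real crowds beyond the model's
own assumptions.

## Numerical and degenerate-input choices

* Nearest-exit ties at initialization are broken uniformly at random, so
  symmetric rooms stay unbiased.
* An agent on a patch that is unreachable for its current exit keeps its
  previous heading; with no usable heading it simply never moves.
* `n_agents = 0` terminates at tick 0 with empty tallies.
* Potential values live in [0, 1] by construction (seed to 1, max-rule
  spread with attenuation < 1, multiplicative decay); a property test
  hammers arbitrary interleavings of seed/spread/decay.
* The engine's per-tick loop is compiled (Rcpp); the R-level operations
  (`decide_exit()`, `select_next_cell()`, the potential operations, …)
  are thin wrappers over the *same* compiled routines, so unit tests and
  full runs exercise identical code paths. All randomness draws from R's
  RNG, so `set.seed()` governs compiled code too.
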