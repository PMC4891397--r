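---
title: "Memory-limited exploration of indoor room graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-limited exploration of indoor room graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roomwalk)
library(dplyr)
```

## The scientific question

How much short-term memory does a walker need to explore an unfamiliar
building about as efficiently as a person does? `roomwalk` studies this
question on a graph abstraction of a multi-floor building: nodes are rooms,
corridors, and staircase landings; edges are doors, corridor links, and
staircases (the only edges allowed to cross between adjacent floors). A
walker's behaviour is reduced to a sequence of room-to-room *hops*, and its
performance to two efficiency curves:

* **coverage after h hops** — the percentage of distinct rooms seen,
  `100 * visited / total` (h = 253 by default, the mean exploration length
  of the human cohorts this design emulates), and
* **hops to a target coverage** — the first hop index at which coverage
  reaches a target (50 % and ~89 % are the interesting targets; the latter
  is where exploration phases typically end).

Three agent families bracket the behavioural space:

1. **Unbiased random walker** — next room uniform among neighbours. Its
   long-run visit share of room r is `degree(r) / (2|E|)`, which makes it
   the natural topography-only baseline.
2. **Perfect m-step memory agent** — a biased walker that refuses to
   re-enter any of the last m rooms while an unremembered neighbour exists;
   when stuck, it backtracks along its remembered path to the nearest
   remembered junction that still has an unexplored direction; when even
   that fails it moves uniformly.
3. **m-th-order Markov agent** — next room sampled from the empirical
   distribution of continuations among corpus subpaths that share the
   walker's last m rooms. This agent inherits whatever regularities *and
   errors* the corpus contains, so it behaves like "the average player with
   an m-step memory".

The Markov order at which the agents' efficiency stops improving estimates
the memory depth expressed in the corpus — the package's headline analysis.
Statistical order-selection criteria are deliberately not used: with a
44-room state space and corpora of a few dozen trajectories they are
unreliable, and order is probed by simulation instead.

## Environments

Environments are `env_graph` objects (tibbles of rooms and edges plus
invariant checks), read and written as GraphML or a small JSON dialect.
Two fixtures ship with the package:

* `fig3_fixture()` — the five-node worked example (rooms C, D, E off
  corridor B, reached from corridor A) on which the Markov construction can
  be traced by hand.
* `palace44_fixture()` — a canonical 44-room, three-floor palace. Its
  wall-level layout is an approximation: the published description of the
  original game map pins down the room count, the floor count, the four
  staircases from the ground floor up (two into Block A, one each into
  Blocks B and C), the single staircase to the top floor, the dead-end dorm
  corridor (rooms D1 and D2) hanging off the Block A main corridor, and
  Block B's on-floor accessibility only through the rooms DB2 and The
  Lounge. Everything the analyses assert structurally depends only on these
  printed facts; remaining names and coordinates are arbitrary labels. The
  fixture is frozen in `inst/extdata/palace44.json` and regenerated
  verbatim by `palace44_fixture()`.

Coordinates are planar metres per floor; a room's 3-D position is
`(x, y, floor * floor_height)` with `floor_height = 4 m` by default. The
vertical spacing only matters for the radius of gyration, and any positive
constant preserves the stabilization rule's behaviour.

## Conventions that needed a decision

**Hops and steps.** A trajectory of n room visits has n − 1 hops. All hop
counts in the package (termination rules, efficiency curves) use this
convention.

**The memory window.** The window holds the last m *previously visited*
rooms, most recent first; the avoided set is the window plus the current
room. With m = 0 the window is empty and the memory agent is exactly the
random walker, stream for stream.

**Backtracking.** When no unremembered neighbour exists, the agent scans
its window from most recent to oldest for a room with a neighbour outside
the remembered set, fixes that junction *and* the escape direction at
decision time, and walks back along the remembered path one hop per step.
Each backtrack hop is a real hop: it is appended to the trajectory and
counted against the hop budget, which keeps efficiency comparisons fair.
The retraced path is loop-erased first — remembered paths contain
duplicates (every excursion into a dead end and back), and retracing them
literally would send the agent back into dead ends it just left. If the
remembered path turns out not to be walkable (possible only for the
forgetful synthetic players below), the route is abandoned and the agent
moves uniformly for that hop.

**Markov fallback.** When the length-m context is unseen, the query drops
to order m − 1 against tables derived from the same corpus, recursing to
order 1; an unseen current room falls back to uniform-over-neighbours.
Simulated agents reach contexts absent at every order, so a total sampling
rule is required; the uniform floor below order 1 is this package's choice
and is flagged here because nothing in the underlying design prescribes it.
Estimation defaults to exploration-phase windows; windows never span
players or phase boundaries (a phase change is a discontinuity in the
game, even when the rooms happen to be adjacent).

## The synthetic cohort generator

No movement logs of the original study are available, so the package ships
a generator whose output has *known, recoverable* structure. Each synthetic
player is a perfect m-step memory agent perturbed by four imperfections,
applied per hop in this order:

1. **Forgetting** — every remembered room is independently dropped from the
   window with probability `p_forget` (default 0.05/hop). This produces the
   burst-like revisit errors that distinguish human-trained Markov agents
   from perfect-memory agents, with a single interpretable parameter.
2. **Decision-point reversal** — with a class-specific probability the
   player turns straight back through the door it entered. The default
   profile (straight corridor 0.05, staircase 0.05, corner 0.08, two-door
   room with visible far door 0.20, with hidden far door 0.40) echoes the
   published decision-point rates; they are generator defaults, not fitted
   values. A drawn reversal abandons any pending backtrack route.
3. **Dead-end pruning** — upon stepping into a short dead-end corridor
   branch whose every room it has already seen, the player immediately
   turns back with probability `p_prune` (default 0.80). Branches are
   auto-detected: a component that hangs off a single branching junction,
   contains a corridor, no staircase landing, and at most four rooms — the
   recognizable "dorm corridor" motif rather than every two-room side
   chain.
4. **Floor-first bias** — while an unremembered same-floor option exists,
   any option that starts a staircase detour (a staircase edge or a
   staircase landing) has its selection weight multiplied by
   `floor_aversion` (default 0.5). The bias acts where the detour starts;
   weighting only the landing-to-landing edge itself would be ineffective,
   because by the time a walker stands on a landing the staircase is
   usually its only unremembered option.

Cohorts default to 44 players exploring to 89 % coverage — the scale and
termination of the study population they emulate (checkpoint mechanics are
abstracted into the coverage-based termination). Timestamps advance 6 s per
hop, which puts default cohorts near the published ~25-minute exploration
phases. With every imperfection switched off, a synthetic player is
stream-identical to the perfect memory agent (and at `m_mem = 0` to the
random walker); this degeneracy chain is asserted in the tests.

What the generator does *not* claim: behavioural fidelity beyond the
recoverable structure above. Passing the recovery tests shows the pipeline
can detect memory depth, reversal rates, and pruning in data that contain
them — not that real players move like this generator.

## Estimating the generator's parameters back

`reversal_rates()` reports, per decision-point class, the fraction of
traversals that exit through the entry door. The raw rate is the
descriptive statistic; for *parameter recovery* it is upward-biased,
because a memory-guided walker at a room whose every alternative exit is
freshly remembered turns back regardless of any door-level bias. The
`exclude_recent` argument drops traversals whose every non-entry neighbour
occurs among the previous m trajectory rooms — an observable proxy for
"the walker had no fresh alternative" — and the conditional rate recovers
the generated probability up to a small residual from forgetting
(forgetting the entry door occasionally makes turning back a "fresh"
option again; with the defaults this adds roughly one to two percentage
points).

`branch_revisit_profile()` follows each player's arrivals at a junction:
the fraction turning into the branch per arrival index, and per entry the
hops until the player is back at the junction. "Immediate exit" defaults to
a window of twice the branch diameter; the pruning probability itself is
recovered by the 1-hop exits among entries whose branch was already fully
visited, which is exactly the generated mechanism.

`visit_ratio()` divides a cohort's normalized visit shares by a baseline
profile, removing node-degree effects; `floor_normalized_visit_ratio()`
restricts the normalization to each floor, which cancels the between-floor
allocation and isolates within-floor preferences. A floor-first strategy
shows up as a difference between the two maps at staircase-adjacent rooms,
and the 1.05 / 0.95 highlight band mirrors the 5 % band used for the
published layout maps.

The random-walk baseline is the *ensemble-average* walker. A single long
walk is a poor stand-in: visit counts along one walk are strongly
autocorrelated (revisits arrive in bursts), and even a 10^5-hop walk
deviates by 10–15 % per room from the stationary law. The tests therefore
pool an ensemble of long walks (10 x 10^5 hops in the unit test, 40 x 10^5
in the acceptance script), which lands within the 5 % band with a
comfortable margin; the closed form `degree / (2|E|)` is available as
`stationary_profile()` whenever an exact baseline is preferable.

## Ensembles, seeds, and the stopping rule

`run_ensemble()` runs replicates seeded by a counter-based spawn from one
master seed, so results are reproducible and replicates independent of
execution order. Besides a fixed replicate count it supports a
stabilization policy patterned on the practice of generating walks until
the variance of the radius of gyration settles: batches of 500, stop when
the running variance changes by less than 1 % (relative) for three
consecutive batches, cap 30,000. The reference analyses used the cap as
their ensemble size; the batch size and tolerance are package defaults
(nothing prescribes exact values), recorded on every result.

The radius of gyration of a trajectory is the root-mean-square distance of
its time-ordered step positions from their centroid, in 3-D with the
`floor_height` spacing (a `dims = "2d"` switch ignores floors; whether the
reference statistic used 2-D or 3-D positions is not stated, so the choice
is explicit and reversible). Revisits are weighted by occurrence, matching
the mobility-literature definition for position time series.

## Problem sizes used by the tests and the acceptance script

These are the package's validation scales, chosen to give the assertions
comfortable statistical margins:

* efficiency sweeps: 2,000 replicates per memory size over
  m ∈ {0, 2, 4, 6, 8, 13} for coverage-after-253-hops and
  hops-to-50 %-coverage; monotonicity asserted within two standard errors;
* memory-depth recovery: one default 44-player cohort with `m_mem = 7`,
  Markov orders 1–10 at 1,000 replicates each; the order-2 to order-7
  improvement must exceed two standard errors while order 8 to 10 stays
  within two (the operational definition of "the curve plateaus near the
  generating depth");
* Markov-vs-perfect comparison: 1,000 replicates at m ∈ {2, 7, 13};
* generator recovery: reversal and pruning rates against exact binomial
  95 % confidence intervals (one cohort in the tests; the acceptance
  script pools five cohorts for a stable point estimate);
* oracle checks: 10^5 two-hop replicates against the exhaustive enumeration
  of two-hop walks on the worked-example star.

## Known limitations

* The palace fixture is a structurally constrained approximation, not the
  original map; analyses that depend on wall-level geometry (true
  line-of-sight, metric path lengths within rooms) are out of scope, and
  door visibility is an annotation, not a ray-cast.
* The memory agent's backtracking semantics (hop accounting, frozen
  target, loop-erasure) are one consistent reading of "goes back to that
  point and continues exploring"; alternatives (teleport-style backtracks,
  re-evaluated targets) would change absolute hop counts, though not the
  qualitative memory-size effects.
* A perfect-memory agent can re-enter an explored dead end once the branch
  has decayed from its window or a backtrack route passes nearby, so
  "never returns" is not an invariant of the model — only rarity relative
  to the random walker is.
* The conditional reversal estimator removes memory-forced reversals but
  not the small forgetting residual described above.
* Markov tables serialised to JSON answer queries at their stored order
  only; full order fallback needs the originating corpus.
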