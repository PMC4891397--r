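# roomwalk

Agent-based tools for quantifying how short-term memory shapes the
exploration of unfamiliar multi-floor buildings.

A building is abstracted as an undirected room graph — nodes are rooms,
corridors and staircase landings with floor indices and coordinates; edges
are doors, corridor links and staircases. Exploration performance is
measured in *hops* (room-to-room transitions) and *coverage*
(`100 × rooms visited / total rooms`). Three agent families bracket the
behavioural space:

* the **unbiased random walker**, whose long-run visit share of room *r*
  is the degree-proportional stationary law `deg(r) / (2|E|)`;
* the **perfect m-step memory agent**, which avoids its last *m* rooms and
  backtracks to remembered unexplored junctions when stuck;
* the **m-th-order Markov agent**, whose next room is drawn from the
  empirical continuation distribution of corpus subpaths matching its last
  *m* rooms (with order fallback m → m−1 → … → 1 → uniform), i.e. the
  "average player" at memory depth *m*.

Because the Markov agent inherits the corpus's regularities *and* errors,
sweeping its order and watching where the exploration-efficiency curve
flattens estimates the memory depth expressed in the data. The package
ships a synthetic-player generator with controlled imperfections
(per-hop forgetting, floor-first staircase aversion, decision-point
reversal probabilities, dead-end pruning) so that the whole pipeline —
including memory-depth recovery — is testable end to end without human
logs. Descriptive statistics include normalized visit shares, visit ratios
against the random-walk baseline (total and floor-normalized), radius of
gyration, decision-point reversal rates, and dead-end revisit profiles.

## A worked example

The five-node toy environment has rooms C, D, E hanging off corridor B.
After the walk A → B → C → B → D → B, an agent with a six-step memory must
move to E (every other neighbour is remembered). A 6th-order Markov agent
instead consults what players did in that exact situation:

```r
library(roomwalk)
library(dplyr)

g <- fig3_fixture()
corpus <- bind_rows(
  tibble(player_id = "b", room_id = c("A","B","C","B","D","B","E"), t = 0:6, phase = "exploration"),
  tibble(player_id = "c", room_id = c("A","B","C","B","D","B","E"), t = 0:6, phase = "exploration"),
  tibble(player_id = "d", room_id = c("A","B","C","B","D","B","A"), t = 0:6, phase = "exploration"))

tab <- build_context_table(corpus, m = 6)
next_room_distribution(tab, c("A","B","C","B","D","B"), g)
#>         A         E
#> 0.3333333 0.6666667
```

Two of the three recorded players continued to E and one returned to A, so
the Markov agent moves to E with probability 2/3 and back to A with 1/3 —
imperfect recollection, inherited from the corpus.

On the full 44-room, three-floor palace fixture, a synthetic cohort and an
efficiency sweep look like this:

```r
palace <- palace44_fixture()
cohort <- generate_cohort(cohort_params(seed = 7), palace)
#> synthetic cohort: 44 players, mean hops 149.5, mean coverage 90.9%

coverage_at_hops(palace, memory_sweep(c(0, 2, 4, 6, 8, 13)),
                 hops = 253, n_replicates = 2000, seed = 1)
#>    m   kind     mean         se    n
#>    0 random 78.78864 0.20149859 2000
#>    2 memory 96.27045 0.11292491 2000
#>    4 memory 97.30909 0.09766106 2000
#>    6 memory 97.48182 0.09683994 2000
#>    8 memory 97.68295 0.09750186 2000
#>   13 memory 98.04091 0.09636677 2000
```

Even two steps of memory lift coverage-after-253-hops from ~79 % to ~96 %,
and the curve saturates as *m* grows. Sweeping Markov agents trained on the
cohort (`markov_sweep(cohort, 1:10)` with `hops_to_coverage(..., target = 50)`)
shows hops-to-half-coverage improving up to roughly the cohort's generating
memory depth (7) and flattening beyond it — the memory-depth recovery
analysis. `autoplot()` methods draw the standard-error curves; `tidy()` and
`glance()` return per-replicate records and one-row summaries.

A thin command-line wrapper exposes the same pipeline
(`simulate`, `sweep`, `analyze`, `generate`, `validate-env`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","roomwalk",package="roomwalk"))')" \
  generate --env fixture:palace44 --n 44 --m-mem 7 --seed 7 --out out/
```

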