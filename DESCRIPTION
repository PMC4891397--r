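Package: roomwalk
Title: Memory-Limited Agents Exploring Indoor Room Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based tools for studying how short-term memory shapes the
    exploration of multi-floor indoor environments represented as room graphs.
    Provides unbiased random walkers, agents with perfect m-step memory, and
    m-th-order Markov agents estimated from trajectory corpora with order
    fallback; a synthetic-player generator with controlled imperfections
    (forgetting, floor-first bias, decision-point reversals, dead-end pruning);
    and the descriptive statistics of exploration efficiency: coverage after a
    fixed number of hops, hops to a target coverage, normalized room-visit
    shares and visit ratios against the random-walk baseline, radius of
    gyration, decision-point reversal rates, and dead-end revisit profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
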