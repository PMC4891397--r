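#' Stabilization policy for replicate ensembles
#'
#' Replicates are generated in batches until the running variance of the
#' radius of gyration changes by less than `tol` (relative) for `consecutive`
#' successive batches, or until `cap` replicates have been generated. The
#' stopping statistic mirrors the practice of generating walk ensembles until
#' the radius-of-gyration variance stabilizes; the batch size, tolerance and
#' cap are package defaults, recorded on every result.
#'
#' @param batch Replicates per batch.
#' @param tol Relative variance-change tolerance.
#' @param consecutive Number of consecutive conforming batches required.
#' @param cap Hard cap on replicates.
#' @return A `stabilization_policy` list.
#' @export
stabilization_policy <- function(batch = 500, tol = 0.01, consecutive = 3,
                                 cap = 30000) {
  if (batch < 1 || cap < batch) abort("need cap >= batch >= 1")
  structure(list(batch = as.integer(batch), tol = tol,
                 consecutive = as.integer(consecutive), cap = as.integer(cap)),
            class = "stabilization_policy")
}

# deterministic per-replicate seed spawned from one master seed (kept < 2^31)
spawn_seed <- function(master, i) {
  x <- (as.double(master) %% 2147483647) * 48271 + as.double(i) * 9973
  as.integer(x %% 2147483647) + 1L
}

#' Run a replicate ensemble of one agent
#'
#' Runs `n_replicates` independent walks (or batches under a
#' [stabilization_policy()]) of the agent described by `agent`, each seeded
#' deterministically from `seed`, and records per replicate the hop count,
#' final coverage, radius of gyration, and truncation flag.
#'
#' @param g The [env_graph].
#' @param agent An [agent_spec()].
#' @param rule A [termination_rule()].
#' @param n_replicates Fixed replicate count; give either this or `policy`.
#' @param policy A [stabilization_policy()].
#' @param seed Master seed.
#' @param start Starting room id (default: the graph's start).
#' @return An `ensemble_result`: a tibble with columns `replicate`, `hops`,
#'   `coverage`, `rog`, `truncated` and attributes `agent`, `rule`, `seed`,
#'   `policy`.
#' @export
run_ensemble <- function(g, agent, rule, n_replicates = NULL, policy = NULL,
                         seed = 1, start = NULL) {
  if (is.null(n_replicates) && is.null(policy)) {
    abort("give `n_replicates` or a stabilization `policy`")
  }
  ix <- env_index(g)
  start <- start %||% (if (!is.na(g$start)) g$start else ix$ids[1])
  start_i <- ix$idx[[start]]
  m_eff <- if (agent$kind == "memory") agent$m else 0L

  one <- function(i) {
    set.seed(spawn_seed(seed, i))
    r <- sim_walk(ix, agent$kind, start_i, rule, m = m_eff, table = agent$table)
    c(hops = r$hops, coverage = r$coverage,
      rog = rog_positions(ix$coords[r$path, , drop = FALSE]),
      truncated = as.numeric(r$truncated))
  }

  if (!is.null(n_replicates)) {
    rec <- vapply(seq_len(n_replicates), one, numeric(4))
  } else {
    rec <- NULL
    conforming <- 0L
    prev_var <- NA_real_
    n <- 0L
    while (n < policy$cap && conforming < policy$consecutive) {
      nb <- min(policy$batch, policy$cap - n)
      batch <- vapply(n + seq_len(nb), one, numeric(4))
      rec <- if (is.null(rec)) batch else cbind(rec, batch)
      n <- n + nb
      v <- stats::var(rec["rog", ])
      if (!is.na(prev_var) && prev_var > 0 &&
          abs(v - prev_var) / prev_var < policy$tol) {
        conforming <- conforming + 1L
      } else {
        conforming <- 0L
      }
      prev_var <- v
    }
  }
  out <- tibble(replicate = seq_len(ncol(rec)),
                hops = as.integer(rec["hops", ]),
                coverage = rec["coverage", ],
                rog = rec["rog", ],
                truncated = rec["truncated", ] > 0)
  attr(out, "agent") <- agent
  attr(out, "rule") <- rule
  attr(out, "seed") <- seed
  attr(out, "policy") <- policy
  class(out) <- c("ensemble_result", class(out))
  out
}

summary_point <- function(x) {
  tibble(mean = mean(x), se = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0,
         n = length(x))
}

#' Mean coverage after a fixed number of hops, per memory size
#'
#' For each agent in `agents`, runs an ensemble with a fixed-hop termination
#' and summarises the final coverage as mean and standard error — the
#' coverage-after-h-hops efficiency curve as a function of memory size.
#'
#' @param g The [env_graph].
#' @param agents A list of [agent_spec()]s (see [memory_sweep()]).
#' @param hops Hop budget per replicate.
#' @param n_replicates Replicates per agent.
#' @param seed Master seed; each agent's ensemble derives its own stream.
#' @param start Starting room id.
#' @return A tibble with one row per agent: `m`, `kind`, `mean`, `se`, `n`,
#'   of class `rw_sweep`.
#' @export
coverage_at_hops <- function(g, agents, hops, n_replicates = 2000, seed = 1,
                             start = NULL) {
  if (hops < 0) abort("`hops` must be >= 0")
  rule <- termination_rule("fixed_hops", threshold = hops, cap = hops)
  rows <- purrr::map2(agents, seq_along(agents), function(a, i) {
    ens <- run_ensemble(g, a, rule, n_replicates = n_replicates,
                        seed = spawn_seed(seed, 7919 * i), start = start)
    bind_cols(tibble(m = a$m, kind = a$kind), summary_point(ens$coverage))
  })
  out <- bind_rows(rows)
  attr(out, "metric") <- "coverage_at_hops"
  attr(out, "hops") <- hops
  class(out) <- c("rw_sweep", class(out))
  out
}

#' Mean hops needed to reach a target coverage, per memory size
#'
#' For each agent, runs an ensemble with a target-coverage termination and
#' summarises the first hop index at which coverage reached the target.
#' Replicates that hit the safety cap without reaching the target are
#' excluded from the summary; their count is reported in the `excluded`
#' column and a message.
#'
#' @inheritParams coverage_at_hops
#' @param target Coverage target in percent, in (0, 100].
#' @param cap Safety cap on hops per replicate.
#' @return A tibble `m`, `kind`, `mean`, `se`, `n`, `excluded`, of class
#'   `rw_sweep`.
#' @export
hops_to_coverage <- function(g, agents, target, n_replicates = 2000, seed = 1,
                             start = NULL, cap = 50000) {
  if (target <= 0 || target > 100) abort("`target` must be in (0, 100]")
  rule <- termination_rule("target_coverage", threshold = target, cap = cap)
  rows <- purrr::map2(agents, seq_along(agents), function(a, i) {
    ens <- run_ensemble(g, a, rule, n_replicates = n_replicates,
                        seed = spawn_seed(seed, 7919 * i), start = start)
    ok <- !ens$truncated
    if (any(!ok)) {
      inform(paste0("hops_to_coverage: excluded ", sum(!ok),
                    " replicate(s) that missed the target before the cap (",
                    a$kind, ", m=", a$m, ")"))
    }
    bind_cols(tibble(m = a$m, kind = a$kind), summary_point(ens$hops[ok]),
              tibble(excluded = sum(!ok)))
  })
  out <- bind_rows(rows)
  attr(out, "metric") <- "hops_to_coverage"
  attr(out, "target") <- target
  class(out) <- c("rw_sweep", class(out))
  out
}

#' Build agent sweeps over memory sizes
#'
#' `memory_sweep()` maps memory sizes to agent specs, using the unbiased
#' random walker for m = 0. `markov_sweep()` estimates one context table per
#' order from a corpus and wraps each in a markov agent spec.
#'
#' @param ms Integer vector of memory sizes.
#' @param corpus Trajectory corpus for `markov_sweep()`.
#' @param orders Integer vector of Markov orders.
#' @param phase Phase filter passed to [build_context_table()].
#' @return A named list of [agent_spec()]s.
#' @export
memory_sweep <- function(ms) {
  specs <- lapply(ms, function(m) {
    if (m == 0) agent_spec("random") else agent_spec("memory", m = m)
  })
  setNames(specs, paste0("m", ms))
}

#' @rdname memory_sweep
#' @export
markov_sweep <- function(corpus, orders, phase = "exploration") {
  specs <- lapply(orders, function(m) {
    agent_spec("markov", table = build_context_table(corpus, m, phase = phase))
  })
  setNames(specs, paste0("m", orders))
}

#' Sensitivity of Markov-agent performance to corpus size
#'
#' Rebuilds the order-m context table on random player subsamples of the
#' corpus and reports the mean hops-to-target-coverage of the resulting
#' Markov agent per subsample fraction — a diagnostic of how much trajectory
#' data the estimation needs.
#'
#' @param corpus Trajectory corpus.
#' @param g The [env_graph].
#' @param m Markov order.
#' @param fractions Subsample fractions in (0, 1].
#' @param target Coverage target in percent.
#' @param n_replicates Replicates per fraction.
#' @param seed Master seed (drives both the subsampling and the ensembles).
#' @param start Starting room id.
#' @return A tibble `fraction`, `n_players`, `subsample_seed`, `mean`, `se`,
#'   `n`, `excluded`.
#' @export
dataset_size_sensitivity <- function(corpus, g, m, fractions, target = 50,
                                     n_replicates = 500, seed = 1, start = NULL) {
  if (any(fractions <= 0 | fractions > 1)) abort("fractions must lie in (0, 1]")
  players <- unique(corpus$player_id)
  rows <- purrr::imap(fractions, function(f, i) {
    n_keep <- floor(f * length(players))
    if (n_keep < 1) abort(paste0("fraction ", f, " yields zero trajectories"))
    sub_seed <- spawn_seed(seed, 104729 + i)
    set.seed(sub_seed)
    keep <- sample(players, n_keep)
    sub <- corpus[corpus$player_id %in% keep, ]
    attr(sub, "provenance") <- attr(corpus, "provenance")
    sweep <- hops_to_coverage(g, markov_sweep(sub, m), target = target,
                              n_replicates = n_replicates,
                              seed = spawn_seed(seed, 224737 + i), start = start)
    bind_cols(tibble(fraction = f, n_players = n_keep, subsample_seed = sub_seed),
              sweep[, c("mean", "se", "n", "excluded")])
  })
  bind_rows(rows)
}
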