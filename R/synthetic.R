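#' Parameters of a synthetic exploration cohort
#'
#' The generator emulates a cohort of players exploring a building with an
#' imperfect short-term memory. Each player is an m-step memory agent whose
#' behaviour is perturbed by controlled, recoverable imperfections:
#' per-hop forgetting of remembered rooms, a floor-first bias against
#' staircases, class-specific reversal probabilities at decision points, and
#' pruning of already-explored dead-end corridors. With every imperfection
#' switched off the player is stream-identical to the perfect m-step memory
#' agent (and, at `m_mem = 0`, to the unbiased random walker).
#'
#' The default reversal profile and prune probability echo the observed
#' behavioural rates at decision points (under 10 percent at plain
#' corridors, staircases, and corners; about 20 percent at two-door rooms
#' with a visible far door; 40 percent with a hidden one; about 80 percent
#' immediate back-out of a known dead-end corridor). They are generator
#' defaults, not fitted values.
#'
#' @param n_players Number of players in the cohort.
#' @param m_mem Memory window length.
#' @param p_forget Per-hop probability that each remembered room is
#'   independently dropped from the window.
#' @param floor_aversion Multiplier in (0, 1] applied to staircase options
#'   while an unexplored same-floor option remains (1 = no bias).
#' @param reversal_profile Named numeric vector of reversal probabilities by
#'   decision-point class; classes absent from the profile reverse only when
#'   the memory rules force it.
#' @param p_prune Probability of immediately turning back after stepping
#'   into a dead-end branch whose every room was already visited.
#' @param target_coverage Coverage percentage at which a player stops.
#' @param cap Safety cap on hops per player.
#' @param seed Master seed of the cohort.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_players = 44, m_mem = 7, p_forget = 0.05,
                          floor_aversion = 0.5,
                          reversal_profile = c(simple_corridor = 0.05,
                                               staircase = 0.05,
                                               simple_corner = 0.08,
                                               room_two_door_visible = 0.20,
                                               room_two_door_hidden = 0.40),
                          p_prune = 0.80, target_coverage = 89,
                          cap = 30000, seed = 1) {
  probs <- c(p_forget, p_prune, reversal_profile)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (floor_aversion <= 0 || floor_aversion > 1) {
    abort("`floor_aversion` must lie in (0, 1]")
  }
  if (m_mem < 0 || m_mem != round(m_mem)) abort("`m_mem` must be a non-negative integer")
  if (n_players < 1) abort("`n_players` must be >= 1")
  if (target_coverage <= 0 || target_coverage > 100) {
    abort("`target_coverage` must be in (0, 100]")
  }
  bad <- setdiff(names(reversal_profile), decision_classes)
  if (length(bad) > 0) {
    abort(paste0("unknown decision class(es) in reversal_profile: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(n_players = as.integer(n_players), m_mem = as.integer(m_mem),
                 p_forget = p_forget, floor_aversion = floor_aversion,
                 reversal_profile = reversal_profile, p_prune = p_prune,
                 target_coverage = target_coverage, cap = as.integer(cap),
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Detect dead-end corridor branches
#'
#' A dead-end branch is a small subgraph that hangs off a single branching
#' junction: removing the junction disconnects it from the rest of the
#' graph. To match the behavioural motif of a recognizable dead-end corridor
#' (rather than every two-room side chain), a component only qualifies when
#' it contains at least one corridor node, no staircase landing, has at most
#' `max_size` rooms (a short corridor stub, not a whole wing), and meets the
#' junction through exactly one room (the branch root).
#'
#' @param g The [env_graph].
#' @param max_size Largest branch size considered.
#' @return A tibble `junction`, `root`, `rooms` (list-column), `size`.
#' @export
dead_end_branches <- function(g, max_size = 4) {
  ix <- env_index(g)
  ig <- as_igraph(g)
  out <- list()
  for (j in which(ix$degree >= 3)) {
    jid <- ix$ids[j]
    sub <- igraph::delete_vertices(ig, jid)
    comp <- igraph::components(sub)
    main <- which.max(comp$csize)
    for (ci in seq_len(comp$no)) {
      if (ci == main) next
      rooms <- names(comp$membership)[comp$membership == ci]
      if (length(rooms) > max_size) next
      cats <- g$rooms$category[match(rooms, g$rooms$id)]
      if (!any(cats == "corridor") || any(cats == "staircase_landing")) next
      roots <- intersect(rooms, env_neighbors(g, jid))
      if (length(roots) != 1) next
      sz <- length(rooms)
      out[[length(out) + 1]] <- tibble(junction = jid, root = roots,
                                       rooms = list(rooms), size = sz)
    }
  }
  if (length(out) == 0) {
    tibble(junction = character(), root = character(), rooms = list(),
           size = integer())
  } else {
    bind_rows(out)
  }
}

# assemble the per-room bias tables the walk engine consumes
syn_context <- function(params, g, ix) {
  cls <- classify_rooms(g)$class
  rev_prob <- numeric(length(ix$ids))
  hit <- !is.na(cls) & cls %in% names(params$reversal_profile)
  rev_prob[hit] <- params$reversal_profile[cls[hit]]
  branch_junction <- integer(length(ix$ids))
  branch_rooms <- vector("list", length(ix$ids))
  if (params$p_prune > 0) {
    br <- dead_end_branches(g)
    for (i in seq_len(nrow(br))) {
      root_i <- ix$idx[[br$root[i]]]
      branch_junction[root_i] <- ix$idx[[br$junction[i]]]
      branch_rooms[[root_i]] <- unname(ix$idx[br$rooms[[i]]])
    }
  }
  list(p_forget = params$p_forget, stair_w = params$floor_aversion,
       rev_prob = rev_prob, p_prune = params$p_prune,
       branch_junction = branch_junction, branch_rooms = branch_rooms)
}

#' Generate one synthetic player's trajectory
#'
#' Runs the imperfect memory walker described by `params` from `start` until
#' it has seen `target_coverage` percent of the rooms. Timestamps advance by
#' six seconds per hop, the typical per-hop pace of an exploration run.
#'
#' @param params A [cohort_params()] object.
#' @param g The [env_graph].
#' @param start Starting room id (default: the graph's start).
#' @param seed Seed for this player.
#' @param player_id Label recorded in the trajectory.
#' @return A trajectory tibble with attributes `truncated` and `seed`.
#' @export
generate_player <- function(params, g, start = NULL, seed = 1,
                            player_id = "p01") {
  ix <- env_index(g)
  start <- start %||% (if (!is.na(g$start)) g$start else ix$ids[1])
  if (!start %in% ix$ids) abort(paste0("start room '", start, "' not in graph"))
  rule <- termination_rule("target_coverage",
                           threshold = params$target_coverage,
                           cap = params$cap)
  syn <- syn_context(params, g, ix)
  set.seed(seed)
  res <- sim_walk(ix, "memory", ix$idx[[start]], rule, m = params$m_mem,
                  syn = syn)
  out <- tibble(player_id = player_id,
                room_id = ix$ids[res$path],
                t = (seq_along(res$path) - 1) * 6,
                phase = "exploration")
  attr(out, "truncated") <- res$truncated
  attr(out, "seed") <- seed
  attr(out, "provenance") <- "synthetic"
  out
}

#' Generate a synthetic cohort
#'
#' Generates `n_players` trajectories with per-player seeds spawned
#' deterministically from the master seed, and reports the cohort's mean hop
#' count and coverage.
#'
#' @inheritParams generate_player
#' @param quiet Suppress the summary message.
#' @return A trajectory corpus tibble (provenance `"synthetic"`) with
#'   attribute `params`.
#' @export
generate_cohort <- function(params, g, start = NULL, quiet = FALSE) {
  players <- sprintf("p%02d", seq_len(params$n_players))
  trajs <- lapply(seq_len(params$n_players), function(i) {
    generate_player(params, g, start = start,
                    seed = spawn_seed(params$seed, i), player_id = players[i])
  })
  out <- bind_rows(trajs)
  attr(out, "provenance") <- "synthetic"
  attr(out, "params") <- params
  hops <- vapply(trajs, n_hops, numeric(1))
  covs <- vapply(trajs, coverage, numeric(1), g = g)
  if (!quiet) {
    inform(sprintf("synthetic cohort: %d players, mean hops %.1f, mean coverage %.1f%%",
                   params$n_players, mean(hops), mean(covs)))
  }
  out
}
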