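#' Termination rules for agent runs
#'
#' @param mode `"full_coverage"` (walk until every room is visited),
#'   `"target_coverage"` (until coverage reaches `threshold` percent), or
#'   `"fixed_hops"` (exactly `threshold` hops).
#' @param threshold Coverage percentage or hop count, depending on `mode`.
#' @param cap Safety cap on hops; a run that hits the cap before its
#'   condition is flagged as truncated.
#' @return A `termination_rule` list.
#' @export
termination_rule <- function(mode = c("full_coverage", "target_coverage", "fixed_hops"),
                             threshold = NULL, cap = 100000) {
  mode <- arg_match(mode)
  if (mode == "full_coverage") threshold <- 100
  if (is.null(threshold) || threshold < 0) abort("`threshold` must be non-negative")
  if (mode == "target_coverage" && (threshold <= 0 || threshold > 100)) {
    abort("coverage target must be in (0, 100]")
  }
  if (mode == "fixed_hops" && cap < threshold) abort("`cap` must be >= fixed hop count")
  structure(list(mode = mode, threshold = threshold, cap = cap),
            class = "termination_rule")
}

#' Agent specifications
#'
#' A lightweight description of one of the three agent families:
#' `"random"` (unbiased random walker), `"memory"` (perfect m-step memory
#' agent), or `"markov"` (m-th-order Markov agent driven by a context table).
#'
#' @param kind Agent family.
#' @param m Memory window length (memory agent) or a label for plotting
#'   (markov agents use their table's order).
#' @param table A `context_table`, required for `kind = "markov"`.
#' @return An `agent_spec` list.
#' @export
agent_spec <- function(kind = c("random", "memory", "markov"), m = 0, table = NULL) {
  kind <- arg_match(kind)
  if (kind == "markov") {
    if (is.null(table)) abort("markov agents need a `table`")
    m <- table$order
  }
  if (kind == "random") m <- 0
  if (m < 0 || m != round(m)) abort("`m` must be a non-negative integer")
  structure(list(kind = kind, m = as.integer(m), table = table),
            class = "agent_spec")
}

# ---- choice primitives (shared by the step functions, the walk engine and
# ---- the synthetic generator so degenerate parameters are stream-identical)

pick_unif <- function(v) v[sample.int(length(v), 1L)]

# loop-erased retrace: input is an adjacent room sequence starting at the
# current room; repeats are cut back so the result is a simple adjacent path
loop_erase <- function(s) {
  out <- integer(0)
  for (v in s) {
    j <- match(v, out)
    if (is.na(j)) out <- c(out, v) else out <- out[seq_len(j)]
  }
  out
}

# One memory-agent decision. window excludes the current room (most recent
# first); the avoided set is window + current. Returns the chosen next room
# and any pending backtrack route (fixed at decision time, loop-erased).
# stair_w < 1 down-weights staircase options while a same-floor candidate
# remains (floor-first bias of the synthetic players).
memory_decide <- function(ix, cur, window, stair_w = 1) {
  nbrs <- ix$adj[[cur]]
  fresh <- !(nbrs %in% window)
  if (any(fresh)) {
    cand <- nbrs[fresh]
    if (stair_w < 1) {
      st <- ix$adj_stair[[cur]][fresh]
      if (any(st) && any(!st)) {
        w <- ifelse(st, stair_w, 1)
        return(list(nxt = cand[sample.int(length(cand), 1L, prob = w)],
                    route = integer(0)))
      }
    }
    return(list(nxt = pick_unif(cand), route = integer(0)))
  }
  avoid <- c(window, cur)
  for (k in seq_along(window)) {
    wn <- ix$adj[[window[k]]]
    out <- wn[!(wn %in% avoid)]
    if (length(out) > 0) {
      seg <- loop_erase(c(cur, window[seq_len(k)]))
      route <- c(seg[-1], pick_unif(out))
      # remembered paths can be broken by forgetting; verify adjacency
      chain <- c(cur, route)
      ok <- TRUE
      for (i in seq_len(length(chain) - 1L)) {
        if (!(chain[i + 1L] %in% ix$adj[[chain[i]]])) { ok <- FALSE; break }
      }
      if (ok) return(list(nxt = route[1], route = route[-1]))
      break
    }
  }
  list(nxt = pick_unif(nbrs), route = integer(0))
}

#' Single steps of the three agent families
#'
#' These expose one decision of each step rule for inspection and testing;
#' [run_agent()] applies the same rules in a loop.
#'
#' `step_random_walker()` draws uniformly among the neighbours of the current
#' room. `step_memory_agent()` (i) prefers neighbours outside the memory
#' window, (ii) otherwise backtracks along the remembered path towards the
#' nearest remembered junction that still has an unexplored direction, and
#' (iii) failing both draws uniformly among all neighbours.
#' `step_markov_agent()` samples from the conditional next-room distribution
#' given the trajectory so far (with order fallback).
#'
#' @param state A list with elements `current` (room id) and, for the memory
#'   agent, `memory` (character vector of previously visited rooms, most
#'   recent first, current room excluded) and optionally `route` (pending
#'   backtrack route); for the Markov agent, `path` (trajectory so far,
#'   oldest first).
#' @param g The [env_graph].
#' @param m Memory window length.
#' @param table A `context_table`.
#' @return The id of the next room.
#' @export
step_random_walker <- function(state, g) {
  ix <- env_index(g)
  cur <- ix$idx[[state$current]]
  if (ix$degree[cur] == 0) abort("current room has no neighbours")
  ix$ids[pick_unif(ix$adj[[cur]])]
}

#' @rdname step_random_walker
#' @export
step_memory_agent <- function(state, m, g) {
  if (m < 0) abort("`m` must be >= 0")
  ix <- env_index(g)
  cur <- ix$idx[[state$current]]
  if (ix$degree[cur] == 0) abort("current room has no neighbours")
  window <- unname(ix$idx[head(state$memory %||% character(0), m)])
  ix$ids[memory_decide(ix, cur, window)$nxt]
}

#' @rdname step_random_walker
#' @export
step_markov_agent <- function(state, table, g) {
  path <- state$path %||% state$current
  if (length(path) == 0) abort("trajectory so far must be non-empty")
  p <- next_room_distribution(table, path, g)
  names(p)[sample.int(length(p), 1L, prob = p)]
}

# ---- walk engine ----------------------------------------------------------

# markov sampler over integer room indices; envs fetched lazily per order
markov_sampler <- function(table, ix) {
  has_corpus <- length(table$seqs) > 0
  function(path, len, cur) {
    top <- min(table$order, len)
    if (has_corpus) {
      for (ord in rev(seq_len(top))) {
        suf <- ix$ids[path[(len - ord + 1L):len]]
        cnt <- ct_counts(table, ord)[[paste(suf, collapse = CTX_SEP)]]
        if (!is.null(cnt)) {
          nm <- names(cnt)[sample.int(length(cnt), 1L, prob = cnt)]
          return(ix$idx[[nm]])
        }
      }
    } else if (top == table$order) {
      suf <- ix$ids[path[(len - top + 1L):len]]
      cnt <- table$cache[[paste0("o", table$order)]][[paste(suf, collapse = CTX_SEP)]]
      if (!is.null(cnt)) {
        nm <- names(cnt)[sample.int(length(cnt), 1L, prob = cnt)]
        return(ix$idx[[nm]])
      }
    }
    pick_unif(ix$adj[[cur]])
  }
}

# Core loop. `syn` carries the synthetic-player imperfections (NULL for the
# ideal agents): p_forget, stair_w, rev_prob (per-room), p_prune,
# branch_junction (per-room root -> junction index, 0 otherwise),
# branch_rooms (list indexed by root). Uses the global RNG stream.
sim_walk <- function(ix, kind, start, rule, m = 0L, table = NULL, syn = NULL) {
  n_rooms <- length(ix$ids)
  cur <- start
  visited <- logical(n_rooms); visited[cur] <- TRUE
  n_vis <- 1L
  need <- if (rule$mode == "full_coverage") n_rooms
          else if (rule$mode == "target_coverage") {
            # tolerance so that e.g. a target of exactly one room's share is
            # already met by the start room
            ceiling(rule$threshold * n_rooms / 100 - 1e-9)
          } else NA_integer_
  cap <- if (rule$mode == "fixed_hops") rule$threshold else rule$cap
  path <- integer(min(cap, 65536L) + 1L); path[1] <- cur; len <- 1L
  window <- integer(0)
  route <- integer(0)
  prev <- 0L
  mk <- if (kind == "markov") markov_sampler(table, ix) else NULL
  hops <- 0L
  truncated <- FALSE
  repeat {
    if (rule$mode == "fixed_hops") {
      if (hops >= rule$threshold) break
    } else if (n_vis >= need) break
    if (hops >= cap) { truncated <- TRUE; break }

    if (!is.null(syn) && syn$p_forget > 0 && length(window) > 0) {
      window <- window[runif(length(window)) >= syn$p_forget]
    }
    nxt <- 0L
    if (!is.null(syn) && prev > 0L) {
      rp <- syn$rev_prob[cur]
      if (rp > 0 && runif(1) < rp) nxt <- prev
      if (nxt == 0L && syn$p_prune > 0) {
        j <- syn$branch_junction[cur]
        if (j > 0L && prev == j && all(visited[syn$branch_rooms[[cur]]]) &&
            runif(1) < syn$p_prune) {
          nxt <- prev
        }
      }
      if (nxt != 0L) route <- integer(0) # a reversal abandons any backtrack
    }
    if (nxt == 0L && length(route) > 0) {
      if (route[1] %in% ix$adj[[cur]]) {
        nxt <- route[1]; route <- route[-1]
      } else route <- integer(0)
    }
    if (nxt == 0L) {
      if (kind == "random") {
        nxt <- pick_unif(ix$adj[[cur]])
      } else if (kind == "markov") {
        nxt <- mk(path, len, cur)
      } else {
        dec <- memory_decide(ix, cur, window,
                             stair_w = if (is.null(syn)) 1 else syn$stair_w)
        nxt <- dec$nxt; route <- dec$route
      }
    }
    if (m > 0L) window <- c(cur, head(window, m - 1L))
    prev <- cur; cur <- nxt
    if (!visited[cur]) { visited[cur] <- TRUE; n_vis <- n_vis + 1L }
    hops <- hops + 1L; len <- len + 1L
    if (len > length(path)) path <- c(path, integer(length(path)))
    path[len] <- cur
  }
  list(path = path[seq_len(len)], truncated = truncated,
       coverage = 100 * n_vis / n_rooms, hops = hops)
}

#' Run one agent to termination
#'
#' Generates a trajectory by repeatedly applying an agent's step rule on `g`
#' until the termination rule fires (or its safety cap is hit, in which case
#' the result carries `truncated = TRUE` as an attribute). Identical seeds
#' and parameters yield identical trajectories.
#'
#' @param g The [env_graph].
#' @param agent An [agent_spec()].
#' @param rule A [termination_rule()].
#' @param start Starting room id; defaults to the graph's designated start.
#' @param seed Integer seed for the run (optional; uses the current RNG
#'   state when missing).
#' @param player_id Label recorded in the trajectory.
#' @param dt Seconds per hop used for the synthetic timestamps.
#' @return A trajectory tibble (`player_id`, `room_id`, `t`, `phase`) with
#'   attributes `truncated`, `agent`, and `seed`.
#' @export
run_agent <- function(g, agent, rule = termination_rule("full_coverage"),
                      start = NULL, seed = NULL, player_id = "agent", dt = 1) {
  ix <- env_index(g)
  start <- start %||% (if (!is.na(g$start)) g$start else ix$ids[1])
  if (!start %in% ix$ids) abort(paste0("start room '", start, "' not in graph"))
  if (!is.null(seed)) set.seed(seed)
  res <- sim_walk(ix, agent$kind, ix$idx[[start]], rule,
                  m = if (agent$kind == "memory") agent$m else 0L,
                  table = agent$table)
  out <- tibble(player_id = player_id,
                room_id = ix$ids[res$path],
                t = (seq_along(res$path) - 1) * dt,
                phase = "exploration")
  attr(out, "truncated") <- res$truncated
  attr(out, "agent") <- agent
  attr(out, "seed") <- seed
  attr(out, "provenance") <- "agent"
  out
}
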