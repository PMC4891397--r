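#' Movement logs and trajectories
#'
#' A trajectory is one player's ordered sequence of room visits; a corpus is a
#' set of trajectories over the same environment, stored as a plain tibble
#' with columns `player_id`, `room_id`, `t` (seconds, non-decreasing within a
#' player), and `phase` (`"exploration"` or `"testing"`). Consecutive rooms of
#' a trajectory must be adjacent in the governing graph, and consecutive
#' identical rooms (sensor-style self-loops) are rejected.
#'
#' @name trajectories
NULL

check_corpus <- function(corpus, g, what = "movement log") {
  need <- c("player_id", "room_id", "t", "phase")
  miss <- setdiff(need, names(corpus))
  if (length(miss) > 0) {
    abort(paste0(what, " missing column(s): ", paste(miss, collapse = ", ")))
  }
  ids <- g$rooms$id
  bad_room <- which(!corpus$room_id %in% ids)
  if (length(bad_room) > 0) {
    abort(paste0(what, " row ", bad_room[1], ": unknown room '",
                 corpus$room_id[bad_room[1]], "'"))
  }
  ix <- env_index(g)
  adj_key <- unlist(lapply(seq_along(ix$adj), function(i) {
    paste(i, ix$adj[[i]])
  }))
  by_player <- split(seq_len(nrow(corpus)), corpus$player_id)
  for (rows in by_player) {
    r <- ix$idx[corpus$room_id[rows]]
    tt <- corpus$t[rows]
    if (any(diff(tt) < 0)) {
      j <- rows[which(diff(tt) < 0)[1] + 1]
      abort(paste0(what, " row ", j, ": time regression"))
    }
    if (length(r) > 1) {
      same <- which(r[-1] == r[-length(r)])
      if (length(same) > 0) {
        j <- rows[same[1] + 1]
        abort(paste0(what, " row ", j, ": consecutive identical rooms (self-loop)"))
      }
      step_key <- paste(r[-length(r)], r[-1])
      bad <- which(!step_key %in% adj_key)
      if (length(bad) > 0) {
        j <- rows[bad[1] + 1]
        abort(paste0(what, " row ", j, ": rooms '",
                     corpus$room_id[rows[bad[1]]], "' and '", corpus$room_id[j],
                     "' are not adjacent"))
      }
    }
  }
  invisible(corpus)
}

#' Read a movement log
#'
#' Reads a CSV with header `player_id,room_id,t,phase` into a trajectory
#' corpus, validating that every room exists in `g`, that consecutive rooms
#' are adjacent, that timestamps never regress, and that no row repeats the
#' previous room.
#'
#' @param path CSV file path.
#' @param g The governing [env_graph].
#' @param provenance Tag recorded on the result (`"human"`, `"synthetic"`,
#'   or `"agent"`).
#' @return A tibble (one row per visit) with attribute `provenance`.
#' @export
read_movement_log <- function(path, g, provenance = "human") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  corpus <- tibble(player_id = as.character(raw$player_id),
                   room_id = as.character(raw$room_id),
                   t = as.numeric(raw$t),
                   phase = as.character(raw$phase))
  check_corpus(corpus, g)
  attr(corpus, "provenance") <- provenance
  corpus
}

#' Write a movement log
#'
#' Inverse of [read_movement_log()]: writes the corpus as an UTF-8 CSV with
#' header `player_id,room_id,t,phase`.
#'
#' @param corpus A trajectory corpus tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_movement_log <- function(corpus, path) {
  utils::write.csv(corpus[, c("player_id", "room_id", "t", "phase")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a directed movement graph from one trajectory
#'
#' The movement graph records, for each ordered pair of rooms, how often and
#' when the player moved between them, together with per-room visit counts
#' f(r). Visit counts sum to the trajectory's step count by construction.
#'
#' @param trajectory Tibble of visits for a single player (columns `room_id`,
#'   `t`; extra columns ignored). Multiple players are an error: movement
#'   graphs are per-player objects.
#' @param g The governing [env_graph] (used for validation).
#' @return A `movement_graph` object: list with `edges` (tibble `from`, `to`,
#'   `n_traversals`, `times` list-column), `visits` (tibble `room_id`,
#'   `visits`), and `n_steps`.
#' @export
build_movement_graph <- function(trajectory, g) {
  if ("player_id" %in% names(trajectory) &&
      length(unique(trajectory$player_id)) > 1) {
    abort("build_movement_graph() takes a single player's trajectory")
  }
  if (nrow(trajectory) < 1) abort("trajectory must have at least one step")
  rooms <- trajectory$room_id
  visits <- count(tibble(room_id = rooms), room_id, name = "visits")
  if (length(rooms) > 1) {
    ed <- tibble(from = rooms[-length(rooms)], to = rooms[-1],
                 t = trajectory$t[-1])
    edges <- ed %>%
      group_by(from, to) %>%
      summarise(n_traversals = n(), times = list(t), .groups = "drop")
  } else {
    edges <- tibble(from = character(), to = character(),
                    n_traversals = integer(), times = list())
  }
  structure(list(edges = edges, visits = visits, n_steps = length(rooms)),
            class = "movement_graph")
}

#' @export
print.movement_graph <- function(x, ...) {
  cat("<movement_graph> ", x$n_steps, " steps, ",
      nrow(x$visits), " rooms visited, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

#' Exploration coverage
#'
#' The percentage of distinct rooms of the environment visited:
#' 100 * (rooms visited) / (total rooms).
#'
#' @param x A trajectory tibble (column `room_id`) or a character vector of
#'   room ids.
#' @param g The [env_graph].
#' @return A single percentage in `[0, 100]`.
#' @export
coverage <- function(x, g) {
  if (nrow(g$rooms) == 0) abort("coverage is undefined on an empty graph")
  rooms <- if (is.character(x)) x else x$room_id
  bad <- setdiff(unique(rooms), g$rooms$id)
  if (length(bad) > 0) {
    abort(paste0("room(s) not in graph: ", paste(bad, collapse = ", ")))
  }
  100 * length(unique(rooms)) / nrow(g$rooms)
}

# hop count of a trajectory: n visits -> n - 1 hops
n_hops <- function(trajectory) max(nrow(trajectory) - 1L, 0L)

# split a corpus into per-player trajectories (list of tibbles)
split_players <- function(corpus) {
  split(corpus, corpus$player_id)
}
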