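#' Normalized room-visit profile
#'
#' The share of all visits that fell on each room: alpha(r) = f(r) / sum f.
#' Shares sum to 1.
#'
#' @param mg A `movement_graph` from [build_movement_graph()].
#' @return A tibble `room_id`, `visits`, `alpha`.
#' @export
normalized_visits <- function(mg) {
  if (nrow(mg$visits) == 0 || sum(mg$visits$visits) == 0) {
    abort("movement graph records no visits")
  }
  mutate(mg$visits, alpha = visits / sum(visits))
}

#' Degree-proportional stationary visit profile of the random walker
#'
#' The long-run visit share of an unbiased random walk on an undirected
#' graph is degree(r) / (2 |E|); this closed form is the natural baseline
#' profile for visit ratios and the oracle for long-walk checks.
#'
#' @param g The [env_graph].
#' @return A tibble `room_id`, `alpha`.
#' @export
stationary_profile <- function(g) {
  ix <- env_index(g)
  tibble(room_id = ix$ids, alpha = ix$degree / (2 * nrow(g$edges)))
}

#' Visit ratio against a baseline profile
#'
#' y(r) = alpha_player(r) / alpha_baseline(r). Dividing by the random-walk
#' baseline removes the effect of node degree: a ratio above 1 means the
#' player visited the room more often than the topography alone explains.
#' Rooms with zero (or missing) baseline share are flagged rather than
#' scored; rooms the player never visited score 0.
#'
#' @param player,baseline Tibbles with columns `room_id`, `alpha` (e.g. from
#'   [normalized_visits()] or [stationary_profile()]).
#' @return A tibble `room_id`, `alpha_player`, `alpha_baseline`, `y`,
#'   `flagged`.
#' @export
visit_ratio <- function(player, baseline) {
  j <- dplyr::full_join(
    rename(player[, c("room_id", "alpha")], alpha_player = alpha),
    rename(baseline[, c("room_id", "alpha")], alpha_baseline = alpha),
    by = "room_id")
  j$alpha_player[is.na(j$alpha_player)] <- 0
  j$flagged <- is.na(j$alpha_baseline) | j$alpha_baseline <= 0
  j$y <- ifelse(j$flagged, NA_real_, j$alpha_player / j$alpha_baseline)
  j
}

#' Floor-normalized visit ratio
#'
#' Recomputes visit shares with denominators restricted to rooms on the same
#' floor before taking the ratio. Because a random walker already visits a
#' floor more or less often purely through the number of staircases serving
#' it, the floor-normalized ratio isolates within-floor preferences from the
#' between-floor allocation — a difference between the two maps is the
#' signature of a floor-first strategy.
#'
#' @inheritParams visit_ratio
#' @param g The [env_graph] (provides each room's floor).
#' @return A tibble `room_id`, `floor`, `alpha_player`, `alpha_baseline`,
#'   `y`, `flagged` (flagged rooms lie on floors without baseline visits or
#'   have zero baseline share).
#' @export
floor_normalized_visit_ratio <- function(player, baseline, g) {
  floors <- g$rooms[, c("id", "floor")]
  renorm <- function(prof, nm) {
    j <- dplyr::left_join(
      rename(prof[, c("room_id", "alpha")], a = alpha),
      rename(floors, room_id = id), by = "room_id") %>%
      group_by(floor) %>%
      mutate(a = a / sum(a)) %>%
      ungroup()
    setNames(j[, c("room_id", "floor", "a")], c("room_id", "floor", nm))
  }
  j <- dplyr::full_join(renorm(player, "alpha_player"),
                        renorm(baseline, "alpha_baseline")[, c("room_id", "alpha_baseline")],
                        by = "room_id")
  j$alpha_player[is.na(j$alpha_player)] <- 0
  j$flagged <- is.na(j$alpha_baseline) | j$alpha_baseline <= 0 | !is.finite(j$alpha_baseline)
  j$y <- ifelse(j$flagged, NA_real_, j$alpha_player / j$alpha_baseline)
  j
}

#' Flag rooms whose visit ratio leaves the neutral band
#'
#' @param ratio A tibble with columns `room_id`, `y`.
#' @param upper,lower Band limits (default the 5 percent band: 1.05 / 0.95).
#' @return `ratio` with an added `highlight` column (`"high"`, `"low"`,
#'   `"neutral"`).
#' @export
highlight_rooms <- function(ratio, upper = 1.05, lower = 0.95) {
  mutate(ratio, highlight = dplyr::case_when(
    is.na(y) ~ NA_character_,
    y > upper ~ "high",
    y < lower ~ "low",
    TRUE ~ "neutral"))
}

decision_classes <- c("simple_corridor", "staircase", "simple_corner",
                      "room_two_door_visible", "room_two_door_hidden",
                      "branching")

#' Classify rooms into decision-point classes
#'
#' Degree-2 locations are the places where the only real decision is whether
#' to press on or turn back: plain corridors (split into straight corridors
#' and corners by annotation), staircase landings, and two-door pass-through
#' rooms (split by whether the far door is visible from the entrance,
#' per the graph's door-visibility annotations). Locations of degree 3 or
#' more are branching junctions; degree-1 rooms offer no decision and get
#' class `NA`.
#'
#' @param g The [env_graph].
#' @return A tibble `room_id`, `category`, `degree`, `class`.
#' @export
classify_rooms <- function(g) {
  ix <- env_index(g)
  deg <- ix$degree
  hidden_at <- unique(g$door_visibility$at[g$door_visibility$visibility == "hidden"])
  annotated <- unique(g$door_visibility$at)
  cls <- character(length(ix$ids))
  unannotated <- character(0)
  for (i in seq_along(ix$ids)) {
    id <- ix$ids[i]
    cat_i <- g$rooms$category[i]
    if (deg[i] <= 1) {
      cls[i] <- NA_character_
    } else if (deg[i] >= 3) {
      cls[i] <- "branching"
    } else if (cat_i == "staircase_landing") {
      cls[i] <- "staircase"
    } else if (cat_i == "corridor") {
      cls[i] <- if (isTRUE(g$rooms$corner[i])) "simple_corner" else "simple_corridor"
    } else {
      if (id %in% hidden_at) {
        cls[i] <- "room_two_door_hidden"
      } else {
        if (!id %in% annotated) unannotated <- c(unannotated, id)
        cls[i] <- "room_two_door_visible"
      }
    }
  }
  if (length(unannotated) > 0) {
    warn(paste0("two-door room(s) without door-visibility annotation, ",
                "classified visible: ", paste(unannotated, collapse = ", ")))
  }
  tibble(room_id = ix$ids, category = g$rooms$category, degree = deg,
         class = cls)
}

#' Reversal rates at decision points
#'
#' For every interior step of every trajectory, a traversal of room r is a
#' reversal when the player leaves through the edge it entered by. Rates are
#' reported per decision-point class; degree-1 rooms (where turning back is
#' forced) are excluded, and triples never span players or phase boundaries.
#'
#' When estimating a walker's *voluntary* turn-back propensity (rather than
#' the raw behavioural rate), traversals where every alternative exit had
#' been visited within the walker's recent past are better excluded: there a
#' memory-guided walker turns back regardless of any door-level bias. Set
#' `exclude_recent` to the memory window length to drop traversals whose
#' every non-entry neighbour occurs among the previous `exclude_recent`
#' rooms of the trajectory.
#'
#' @param corpus Trajectory corpus tibble.
#' @param g The [env_graph].
#' @param phase Optional phase filter.
#' @param exclude_recent Optional integer; see above. `NULL` (default) keeps
#'   every traversal.
#' @return A tibble `class`, `n_traversals`, `n_reversals`, `rate`.
#' @export
reversal_rates <- function(corpus, g, phase = NULL, exclude_recent = NULL) {
  cls <- setNames(classify_rooms(g)$class, g$rooms$id)
  ix <- env_index(g)
  seqs <- corpus_sequences(corpus, phase)
  at <- character(0); rev_ <- logical(0)
  for (s in seqs) {
    L <- length(s)
    if (L < 3) next
    mid <- s[2:(L - 1)]
    keep <- !is.na(cls[mid])
    if (!is.null(exclude_recent)) {
      si <- unname(ix$idx[s])
      for (i in which(keep)) {
        pos <- i + 1L # position of the traversed room in s
        alts <- setdiff(ix$adj[[si[pos]]], si[pos - 1L])
        recent <- si[max(1L, pos - exclude_recent):(pos - 1L)]
        if (length(alts) > 0 && all(alts %in% recent)) keep[i] <- FALSE
      }
    }
    at <- c(at, mid[keep])
    rev_ <- c(rev_, (s[1:(L - 2)] == s[3:L])[keep])
  }
  if (length(at) == 0) {
    return(tibble(class = character(), n_traversals = integer(),
                  n_reversals = integer(), rate = numeric()))
  }
  tibble(class = unname(cls[at]), reversed = rev_) %>%
    group_by(class) %>%
    summarise(n_traversals = n(), n_reversals = sum(reversed),
              rate = mean(reversed), .groups = "drop")
}

# rms distance to the centroid of a positions matrix
rog_positions <- function(pos) {
  if (nrow(pos) == 0) return(0)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums((pos - matrix(ctr, nrow(pos), ncol(pos), byrow = TRUE))^2)))
}

#' Radius of gyration of a trajectory
#'
#' The root-mean-square distance of the walker's time-ordered step positions
#' from their centroid. Positions are the room coordinates, lifted to 3-D
#' with `floor * floor_height` as the vertical component (set
#' `dims = "2d"` to ignore floors). Revisits are weighted by occurrence.
#'
#' @param trajectory Trajectory tibble (column `room_id`).
#' @param g The [env_graph].
#' @param dims `"3d"` (default) or `"2d"`.
#' @return Radius of gyration in metres.
#' @export
radius_of_gyration <- function(trajectory, g, dims = c("3d", "2d")) {
  dims <- arg_match(dims)
  if (nrow(trajectory) < 1) abort("trajectory must have at least one step")
  ix <- env_index(g)
  pos <- ix$coords[ix$idx[trajectory$room_id], , drop = FALSE]
  if (dims == "2d") pos <- pos[, 1:2, drop = FALSE]
  rog_positions(pos)
}

#' Entry and immediate-exit profile of a dead-end branch
#'
#' Follows every player's arrivals at a junction and their behaviour towards
#' a dead-end branch hanging off it: for the k-th arrival at the junction,
#' whether the player turned into the branch; and for each branch entry,
#' how many hops until the player was back at the junction and whether the
#' whole branch had already been visited before that entry. "Immediate exit"
#' means returning within `exit_window` hops (default twice the branch
#' diameter; an entry followed by a straight reversal exits in 1 hop).
#'
#' @param corpus Trajectory corpus tibble.
#' @param g The [env_graph].
#' @param junction Room id of the junction.
#' @param branch Character vector of branch room ids (a connected dead-end
#'   subgraph reachable from the rest of the graph only through `junction`).
#' @param phase Optional phase filter.
#' @param exit_window Hops within which a return counts as immediate.
#' @return A `branch_profile` object: list with `arrivals` (per junction
#'   arrival: `player_id`, `k`, `entered`), `entries` (per branch entry:
#'   `player_id`, `k`, `prior_full_visit`, `hops_to_exit`, `immediate_exit`)
#'   and `summary` (per-k entry fractions).
#' @export
branch_revisit_profile <- function(corpus, g, junction, branch, phase = NULL,
                                   exit_window = NULL) {
  ids <- g$rooms$id
  stopifnot(junction %in% ids, all(branch %in% ids))
  nb_j <- env_neighbors(g, junction)
  if (!any(branch %in% nb_j)) abort("junction is not adjacent to the branch")
  ig <- as_igraph(g)
  sub <- igraph::induced_subgraph(ig, branch)
  if (igraph::count_components(sub) != 1) abort("branch rooms must be connected")
  if (is.null(exit_window)) {
    exit_window <- max(2 * igraph::diameter(sub, unconnected = FALSE), 2)
  }
  arrivals <- list(); entries <- list()
  for (traj in split_players(corpus)) {
    pid <- traj$player_id[1]
    for (s in corpus_sequences(traj, phase)) {
      L <- length(s)
      seen <- character(0)
      k <- 0L
      for (i in seq_len(L)) {
        if (s[i] == junction && i < L) {
          k <- k + 1L
          entered <- s[i + 1] %in% branch
          arrivals[[length(arrivals) + 1]] <-
            tibble(player_id = pid, k = k, entered = entered)
          if (entered) {
            back <- which(s[(i + 1):L] == junction)
            hte <- if (length(back) > 0) back[1] - 1L else NA_integer_
            entries[[length(entries) + 1]] <- tibble(
              player_id = pid, k = k,
              prior_full_visit = all(branch %in% seen),
              hops_to_exit = hte,
              immediate_exit = !is.na(hte) & hte <= exit_window)
          }
        }
        seen <- union(seen, s[i])
      }
    }
  }
  arrivals <- if (length(arrivals)) bind_rows(arrivals) else
    tibble(player_id = character(), k = integer(), entered = logical())
  entries <- if (length(entries)) bind_rows(entries) else
    tibble(player_id = character(), k = integer(), prior_full_visit = logical(),
           hops_to_exit = integer(), immediate_exit = logical())
  summary <- arrivals %>%
    group_by(k) %>%
    summarise(n = n(), entry_fraction = mean(entered), .groups = "drop")
  structure(list(arrivals = arrivals, entries = entries, summary = summary,
                 junction = junction, branch = branch,
                 exit_window = exit_window),
            class = "branch_profile")
}

#' @export
print.branch_profile <- function(x, ...) {
  cat("<branch_profile> junction '", x$junction, "', branch {",
      paste(x$branch, collapse = ", "), "}\n", sep = "")
  cat(nrow(x$arrivals), " junction arrivals, ", nrow(x$entries),
      " branch entries (exit window ", x$exit_window, " hops)\n", sep = "")
  invisible(x)
}
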