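#' Construct an indoor environment graph
#'
#' An `env_graph` is the arena every agent moves on: an undirected, connected
#' graph whose nodes are rooms, corridors, and staircase landings on one or
#' more floors, and whose edges are doors, corridor links, or staircases.
#' Staircase edges are the only edges allowed to join different (adjacent)
#' floors; every other edge must stay on one floor.
#'
#' @param rooms A data frame with one row per room and columns `id`
#'   (unique short string), `name` (display string), `floor` (integer, 0 =
#'   ground), `block` (optional label, `NA` allowed), `x`, `y` (planar metres),
#'   `category` (one of `"room"`, `"corridor"`, `"staircase_landing"`), and
#'   optionally `corner` (logical; marks a degree-2 corridor as a corner for
#'   decision-point classification).
#' @param edges A data frame with columns `from`, `to` (room ids) and
#'   `link_type` (one of `"door"`, `"corridor"`, `"staircase"`).
#' @param floor_height Metres of vertical separation per floor level; used
#'   only when room positions are lifted to 3-D (radius of gyration).
#' @param door_visibility Optional data frame with columns `at` (room id),
#'   `from_edge`, `to_edge` (neighbouring room ids identifying the two doors),
#'   and `visibility` (`"visible"` or `"hidden"`): whether the far door is in
#'   view when entering through the near one.
#' @param start Optional id of the default starting room for agents.
#' @param check If `TRUE` (default) stop on any violated invariant.
#' @return An object of class `env_graph`.
#' @seealso [validate_environment()], [load_environment()],
#'   [palace44_fixture()], [fig3_fixture()]
#' @export
env_graph <- function(rooms, edges, floor_height = 4,
                      door_visibility = NULL, start = NULL, check = TRUE) {
  rooms <- as_tibble(rooms)
  edges <- as_tibble(edges)
  if (!all(c("id", "floor", "x", "y", "category") %in% names(rooms))) {
    abort("`rooms` needs columns id, floor, x, y, category")
  }
  if (!"name" %in% names(rooms)) rooms$name <- rooms$id
  if (!"block" %in% names(rooms)) rooms$block <- NA_character_
  if (!"corner" %in% names(rooms)) rooms$corner <- FALSE
  rooms$corner[is.na(rooms$corner)] <- FALSE
  rooms <- rooms[, c("id", "name", "floor", "block", "x", "y", "category", "corner")]
  rooms$id <- as.character(rooms$id)
  rooms$floor <- as.integer(rooms$floor)
  rooms$x <- as.numeric(rooms$x)
  rooms$y <- as.numeric(rooms$y)

  if (!all(c("from", "to", "link_type") %in% names(edges))) {
    abort("`edges` needs columns from, to, link_type")
  }
  edges <- edges[, c("from", "to", "link_type")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)

  if (is.null(door_visibility)) {
    door_visibility <- tibble(at = character(), from_edge = character(),
                              to_edge = character(), visibility = character())
  } else {
    door_visibility <- as_tibble(door_visibility)[
      , c("at", "from_edge", "to_edge", "visibility")]
  }

  g <- structure(
    list(rooms = rooms, edges = edges, floor_height = as.numeric(floor_height),
         door_visibility = door_visibility,
         start = if (is.null(start)) NA_character_ else as.character(start)),
    class = "env_graph"
  )
  if (check) {
    rep <- validate_environment(g)
    if (nrow(rep) > 0) {
      abort(paste0("invalid environment graph:\n",
                   paste0("- ", rep$message, collapse = "\n")))
    }
  }
  g
}

room_categories <- c("room", "corridor", "staircase_landing")
link_types <- c("door", "corridor", "staircase")

#' Validate an environment graph
#'
#' Checks every structural invariant of the room-graph model and reports
#' (rather than raises) the violations: duplicate or dangling ids, unknown
#' categories or link types, self-loops, cross-floor non-staircase edges,
#' same-floor or non-adjacent-floor staircase edges, disconnection, and
#' door-visibility records that do not reference incident edges.
#'
#' @param g An [env_graph] (checking is skipped during construction so that
#'   deliberately broken graphs can be inspected).
#' @return A tibble with columns `rule`, `element`, `message`; zero rows iff
#'   the graph is valid.
#' @export
validate_environment <- function(g) {
  bad <- list()
  note <- function(rule, element, message) {
    bad[[length(bad) + 1]] <<- tibble(rule = rule, element = element,
                                      message = message)
  }
  rooms <- g$rooms; edges <- g$edges
  dup <- rooms$id[duplicated(rooms$id)]
  for (d in unique(dup)) note("unique_id", d, paste0("duplicate room id '", d, "'"))
  for (r in rooms$id[rooms$floor < 0]) note("floor", r, paste0("room '", r, "' has negative floor"))
  for (r in rooms$id[!rooms$category %in% room_categories]) {
    note("category", r, paste0("room '", r, "' has unknown category"))
  }
  if (!is.finite(g$floor_height) || g$floor_height <= 0) {
    note("floor_height", NA_character_, "floor_height must be > 0")
  }
  floor_of <- setNames(rooms$floor, rooms$id)
  for (i in seq_len(nrow(edges))) {
    e <- edges[i, ]
    lab <- paste0(e$from, "--", e$to)
    if (!e$from %in% rooms$id || !e$to %in% rooms$id) {
      note("dangling_edge", lab, paste0("edge ", lab, " references an undeclared room"))
      next
    }
    if (e$from == e$to) note("self_loop", lab, paste0("edge ", lab, " is a self-loop"))
    if (!e$link_type %in% link_types) {
      note("link_type", lab, paste0("edge ", lab, " has unknown link_type '", e$link_type, "'"))
      next
    }
    df <- floor_of[[e$from]]; dt <- floor_of[[e$to]]
    if (e$link_type == "staircase") {
      if (abs(df - dt) != 1L) {
        note("staircase_floor", lab,
             paste0("staircase edge ", lab, " must join adjacent floors (", df, " vs ", dt, ")"))
      }
    } else if (df != dt) {
      note("cross_floor", lab,
           paste0(e$link_type, " edge ", lab, " joins different floors (", df, " vs ", dt, ")"))
    }
  }
  ek <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  for (k in unique(ek[duplicated(ek)])) {
    note("duplicate_edge", k, paste0("duplicate edge ", k))
  }
  ok_edges <- edges$from %in% rooms$id & edges$to %in% rooms$id
  if (nrow(rooms) > 0) {
    ig <- igraph::graph_from_data_frame(edges[ok_edges, c("from", "to")],
                                        directed = FALSE,
                                        vertices = rooms["id"])
    if (igraph::count_components(ig) > 1) {
      note("connected", NA_character_, "graph is not connected")
    }
  }
  if (!is.na(g$start) && !g$start %in% rooms$id) {
    note("start", g$start, paste0("start room '", g$start, "' not in graph"))
  }
  dv <- g$door_visibility
  if (nrow(dv) > 0) {
    for (i in seq_len(nrow(dv))) {
      at <- dv$at[i]
      nb <- env_neighbors(g, at)
      for (side in c(dv$from_edge[i], dv$to_edge[i])) {
        if (!side %in% nb) {
          note("door_visibility", at,
               paste0("door_visibility at '", at, "' references non-incident edge to '", side, "'"))
        }
      }
      if (!dv$visibility[i] %in% c("visible", "hidden")) {
        note("door_visibility", at,
             paste0("door_visibility at '", at, "' has unknown value '", dv$visibility[i], "'"))
      }
    }
  }
  if (length(bad) == 0) {
    tibble(rule = character(), element = character(), message = character())
  } else {
    bind_rows(bad)
  }
}

#' @export
print.env_graph <- function(x, ...) {
  cat("<env_graph> ", nrow(x$rooms), " rooms, ", nrow(x$edges), " edges, ",
      length(unique(x$rooms$floor)), " floor(s)\n", sep = "")
  if (!is.na(x$start)) cat("start: ", x$start, "\n", sep = "")
  invisible(x)
}

#' Convert an environment graph to igraph
#'
#' @param g An [env_graph].
#' @return An undirected [igraph::igraph] with the room attributes attached.
#' @export
as_igraph <- function(g) {
  v <- g$rooms
  names(v)[names(v) == "name"] <- "label" # igraph reserves "name" for the id
  igraph::graph_from_data_frame(g$edges, directed = FALSE, vertices = v)
}

# neighbours of one room (character ids)
env_neighbors <- function(g, id) {
  c(g$edges$to[g$edges$from == id], g$edges$from[g$edges$to == id])
}

# Fast integer-indexed view used by the simulation loops:
# ids, id->index map, adjacency list (integer), parallel staircase flags,
# floor vector, 3-D coordinate matrix.
env_index <- function(g) {
  ids <- g$rooms$id
  idx <- setNames(seq_along(ids), ids)
  from <- idx[g$edges$from]; to <- idx[g$edges$to]
  stair <- g$edges$link_type == "staircase"
  landing <- g$rooms$category == "staircase_landing"
  adj <- vector("list", length(ids))
  adj_stair <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    a <- c(to[from == i], from[to == i])
    s <- c(stair[from == i], stair[to == i])
    adj[[i]] <- unname(a)
    # a "staircase option": stepping onto the staircase itself or onto one
    # of its landings (the floor-first bias acts where the detour starts)
    adj_stair[[i]] <- unname(s | landing[a])
  }
  coords <- cbind(g$rooms$x, g$rooms$y, g$rooms$floor * g$floor_height)
  list(ids = ids, idx = idx, adj = adj, adj_stair = adj_stair,
       floor = g$rooms$floor, coords = coords,
       degree = lengths(adj))
}

#' Read an environment graph from file
#'
#' Two formats are supported: the package's JSON dialect (top-level keys
#' `floor_height`, `start`, `rooms`, `edges`, `door_visibility`) and GraphML
#' with node attributes `name`, `floor`, `block`, `category`, `x`, `y`,
#' `corner` and edge attribute `link_type`. The JSON writer and reader
#' round-trip byte-identically.
#'
#' @param path Path to a `.json` or `.graphml` file.
#' @return A validated [env_graph].
#' @export
load_environment <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    load_environment_json(path)
  } else if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    load_environment_graphml(path)
  } else {
    abort("unrecognised environment format (expected .json or .graphml)")
  }
}

load_environment_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (k in c("rooms", "edges")) {
    if (is.null(x[[k]])) abort(paste0("environment JSON missing key '", k, "'"))
  }
  rooms <- as_tibble(x$rooms)
  need <- c("id", "floor", "x", "y", "category")
  miss <- setdiff(need, names(rooms))
  if (length(miss) > 0) {
    abort(paste0("room records missing attribute(s): ", paste(miss, collapse = ", ")))
  }
  edges <- as_tibble(x$edges)
  if (!all(c("from", "to", "link_type") %in% names(edges))) {
    abort("edge records need attributes from, to, link_type")
  }
  dv <- NULL
  if (!is.null(x$door_visibility) && length(x$door_visibility) > 0) {
    dv <- as_tibble(x$door_visibility)
  }
  env_graph(rooms, edges,
            floor_height = x$floor_height %||% 4,
            door_visibility = dv,
            start = x$start)
}

load_environment_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(ig)
  need <- c("name", "floor", "category", "x", "y")
  miss <- setdiff(need, names(va))
  if (length(miss) > 0) {
    abort(paste0("GraphML nodes missing attribute(s): ", paste(miss, collapse = ", ")))
  }
  rooms <- tibble(
    id = va$name,
    name = va$label %||% va$name,
    floor = as.integer(va$floor),
    block = if (is.null(va$block)) NA_character_ else {
      dplyr::na_if(dplyr::na_if(va$block, ""), "NA")
    },
    x = as.numeric(va$x), y = as.numeric(va$y),
    category = va$category,
    corner = if (is.null(va$corner)) FALSE else as.logical(va$corner)
  )
  el <- igraph::as_edgelist(ig, names = TRUE)
  lt <- igraph::edge_attr(ig, "link_type")
  if (is.null(lt)) abort("GraphML edges missing attribute link_type")
  edges <- tibble(from = el[, 1], to = el[, 2], link_type = lt)
  ga <- igraph::graph_attr(ig)
  dv <- NULL
  if (!is.null(ga$door_visibility) && nzchar(ga$door_visibility)) {
    dv <- as_tibble(jsonlite::fromJSON(ga$door_visibility))
  }
  env_graph(rooms, edges,
            floor_height = ga$floor_height %||% 4,
            door_visibility = dv,
            start = if (is.null(ga$start) || !nzchar(ga$start)) NULL else ga$start)
}

#' Write an environment graph to file
#'
#' @param g An [env_graph].
#' @param path Destination `.json` or `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(g, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(environment_json(g), path)
  } else if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    ig <- as_igraph(g)
    ig <- igraph::set_graph_attr(ig, "floor_height", g$floor_height)
    ig <- igraph::set_graph_attr(ig, "start", if (is.na(g$start)) "" else g$start)
    dv <- if (nrow(g$door_visibility) > 0) {
      as.character(jsonlite::toJSON(g$door_visibility, auto_unbox = FALSE))
    } else ""
    ig <- igraph::set_graph_attr(ig, "door_visibility", dv)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    abort("unrecognised environment format (expected .json or .graphml)")
  }
  invisible(path)
}

# canonical JSON serialisation (used by the writer and the packaged fixtures,
# so that write(load(x)) is byte-identical to x)
environment_json <- function(g) {
  x <- list(
    floor_height = g$floor_height,
    start = if (is.na(g$start)) NULL else g$start,
    rooms = g$rooms,
    edges = g$edges,
    door_visibility = g$door_visibility
  )
  jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE, pretty = 2,
                   digits = NA, na = "null")
}
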