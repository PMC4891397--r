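#' Estimate an m-th-order context table from a trajectory corpus
#'
#' Slides a length-(m+1) window over every (phase-filtered) trajectory and
#' counts, for each length-m room context, how often each next room follows.
#' Windows never span trajectory boundaries. The context of a step is the
#' last m rooms visited *including* the current one, so querying the table
#' with a recent path answers "given these last m rooms, where did players go
#' next?".
#'
#' Estimation defaults to the exploration phase, the phase in which unguided
#' exploration happens; pass `phase = NULL` to use all steps.
#'
#' @param corpus Trajectory corpus tibble (columns `player_id`, `room_id`,
#'   `t`, `phase`).
#' @param m Markov order (positive integer).
#' @param phase Optional phase filter; default `"exploration"`.
#' @return A `context_table` object. Lower-order tables needed for fallback
#'   are derived lazily from the same corpus and cached.
#' @export
build_context_table <- function(corpus, m, phase = "exploration") {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer")
  }
  m <- as.integer(m)
  if (nrow(corpus) == 0) abort("corpus is empty")
  seqs <- corpus_sequences(corpus, phase)
  tab <- structure(
    list(order = m,
         seqs = seqs,
         cache = new.env(parent = emptyenv()),
         provenance = attr(corpus, "provenance") %||% "unknown",
         n_trajectories = length(seqs),
         phase = phase),
    class = "context_table"
  )
  # force the top-order counts
  ct_counts(tab, m)
  tab
}

# per-player, per-phase-run room sequences (windows must not span phase
# boundaries or players)
corpus_sequences <- function(corpus, phase) {
  out <- list()
  for (traj in split_players(corpus)) {
    runs <- split(traj$room_id, cumsum(c(TRUE, diff(as.integer(factor(traj$phase))) != 0)))
    ph <- split(traj$phase, cumsum(c(TRUE, diff(as.integer(factor(traj$phase))) != 0)))
    for (i in seq_along(runs)) {
      if (is.null(phase) || ph[[i]][1] == phase) out[[length(out) + 1]] <- runs[[i]]
    }
  }
  out
}

CTX_SEP <- "\x1f"

# counts environment for a given order: key = context ids joined by CTX_SEP,
# value = named integer vector of next-room counts
ct_counts <- function(tab, ord) {
  key <- paste0("o", ord)
  if (!is.null(tab$cache[[key]])) return(tab$cache[[key]])
  e <- new.env(parent = emptyenv())
  ctx_list <- list(); nxt_list <- list()
  for (s in tab$seqs) {
    L <- length(s)
    if (L <= ord) next
    starts <- seq_len(L - ord)
    ctx <- do.call(paste, c(lapply(seq_len(ord) - 1L, function(k) s[starts + k]),
                            sep = CTX_SEP))
    ctx_list[[length(ctx_list) + 1]] <- ctx
    nxt_list[[length(nxt_list) + 1]] <- s[starts + ord]
  }
  all_ctx <- unlist(ctx_list); all_nxt <- unlist(nxt_list)
  if (length(all_ctx) > 0) {
    sp <- split(all_nxt, all_ctx)
    for (k in names(sp)) {
      tb <- base::table(sp[[k]])
      e[[k]] <- setNames(as.integer(tb), names(tb))
    }
  }
  tab$cache[[key]] <- e
  e
}

#' @export
print.context_table <- function(x, ...) {
  e <- ct_counts(x, x$order)
  cat("<context_table> order ", x$order, ", ",
      length(ls(e)), " contexts from ", x$n_trajectories,
      " trajectories (", x$provenance, ")\n", sep = "")
  invisible(x)
}

#' Conditional next-room distribution with order fallback
#'
#' Looks up the length-m suffix of `recent_path` in the context table. If the
#' context was never observed, the query falls back to the length-(m-1)
#' suffix against the order-(m-1) table derived from the same corpus, and so
#' on down to order 1. If even the current room was never observed (or the
#' table was read from JSON without its corpus), the distribution is uniform
#' over the current room's neighbours in `g`.
#'
#' @param table A `context_table` from [build_context_table()].
#' @param recent_path Character vector of recently visited rooms, most recent
#'   last (the current room is the last element).
#' @param g The [env_graph] (for the uniform-over-neighbours floor).
#' @return A named numeric vector of probabilities summing to 1.
#' @export
next_room_distribution <- function(table, recent_path, g) {
  if (length(recent_path) == 0) abort("`recent_path` must be non-empty")
  cur <- recent_path[length(recent_path)]
  if (!cur %in% g$rooms$id) abort(paste0("room '", cur, "' not in graph"))
  top <- min(table$order, length(recent_path))
  if (length(table$seqs) > 0) {
    for (ord in rev(seq_len(top))) {
      suf <- tail(recent_path, ord)
      cnt <- ct_counts(table, ord)[[paste(suf, collapse = CTX_SEP)]]
      if (!is.null(cnt)) return(cnt / sum(cnt))
    }
  } else {
    # deserialised table: only the stored order is available
    suf <- tail(recent_path, table$order)
    if (length(suf) == table$order) {
      cnt <- table$cache[[paste0("o", table$order)]][[paste(suf, collapse = CTX_SEP)]]
      if (!is.null(cnt)) return(cnt / sum(cnt))
    }
  }
  nb <- env_neighbors(g, cur)
  setNames(rep(1 / length(nb), length(nb)), sort(nb))
}

#' Serialise a context table to JSON
#'
#' Writes `{"order": m, "contexts": [{"path": [...], "next": {room: count}}]}`.
#' A table read back with [read_context_table()] answers queries at its stored
#' order only; order fallback needs the originating corpus.
#'
#' @param table A `context_table`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_context_table <- function(table, path) {
  e <- ct_counts(table, table$order)
  keys <- sort(ls(e))
  contexts <- lapply(keys, function(k) {
    list(path = strsplit(k, CTX_SEP, fixed = TRUE)[[1]],
         "next" = as.list(e[[k]]))
  })
  jsonlite::write_json(list(order = table$order, contexts = contexts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_context_table
#' @export
read_context_table <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  e <- new.env(parent = emptyenv())
  for (ctx in x$contexts) {
    key <- paste(unlist(ctx$path), collapse = CTX_SEP)
    e[[key]] <- unlist(ctx[["next"]])
  }
  cache <- new.env(parent = emptyenv())
  cache[[paste0("o", x$order)]] <- e
  structure(list(order = as.integer(x$order), seqs = list(), cache = cache,
                 provenance = "deserialised", n_trajectories = NA_integer_,
                 phase = NULL),
            class = "context_table")
}
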