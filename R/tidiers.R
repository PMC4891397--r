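#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-replicate ensemble records
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return The per-replicate tibble (`replicate`, `hops`, `coverage`, `rog`,
#'   `truncated`) without the result class.
#' @export
tidy.ensemble_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ensemble_result")
  out
}

#' One-row ensemble summary
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A tibble with the agent description, replicate count, means and
#'   standard errors of coverage, hops and radius of gyration, and the
#'   truncation count.
#' @export
glance.ensemble_result <- function(x, ...) {
  agent <- attr(x, "agent")
  n <- nrow(x)
  se <- function(v) if (n > 1) sd(v) / sqrt(n) else 0
  tibble(kind = agent$kind, m = agent$m, n = n,
         mean_coverage = mean(x$coverage), se_coverage = se(x$coverage),
         mean_hops = mean(x$hops), se_hops = se(x$hops),
         mean_rog = mean(x$rog), se_rog = se(x$rog),
         n_truncated = sum(x$truncated))
}

#' Tidy a context table into (context, next room, count) rows
#'
#' @param x A `context_table`.
#' @param ... Unused.
#' @return A tibble `context` (rooms joined by `" > "`), `next_room`, `n`.
#' @export
tidy.context_table <- function(x, ...) {
  e <- ct_counts(x, x$order)
  keys <- sort(ls(e))
  rows <- lapply(keys, function(k) {
    cnt <- e[[k]]
    tibble(context = gsub(CTX_SEP, " > ", k, fixed = TRUE),
           next_room = names(cnt), n = as.integer(cnt))
  })
  if (length(rows) == 0) {
    tibble(context = character(), next_room = character(), n = integer())
  } else {
    bind_rows(rows)
  }
}

#' @rdname tidy.context_table
#' @export
glance.context_table <- function(x, ...) {
  e <- ct_counts(x, x$order)
  keys <- ls(e)
  tibble(order = x$order, n_contexts = length(keys),
         n_windows = sum(vapply(keys, function(k) sum(e[[k]]), numeric(1))),
         n_trajectories = x$n_trajectories)
}

#' Tidy a movement graph into its directed edge table
#'
#' @param x A `movement_graph`.
#' @param ... Unused.
#' @return The edges tibble (`from`, `to`, `n_traversals`, `times`).
#' @export
tidy.movement_graph <- function(x, ...) x$edges

#' @rdname tidy.movement_graph
#' @export
glance.movement_graph <- function(x, ...) {
  tibble(n_steps = x$n_steps, n_rooms = nrow(x$visits),
         n_edges = nrow(x$edges))
}

#' Tidy a branch-revisit profile into its per-arrival summary
#'
#' @param x A `branch_profile`.
#' @param ... Unused.
#' @return The per-k summary tibble (`k`, `n`, `entry_fraction`).
#' @export
tidy.branch_profile <- function(x, ...) x$summary
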