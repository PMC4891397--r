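#' Plot an ensemble's coverage distribution
#'
#' @param object An `ensemble_result`.
#' @param metric Which per-replicate quantity to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ensemble_result <- function(object, metric = c("coverage", "hops", "rog"),
                                     ...) {
  metric <- arg_match(metric)
  agent <- attr(object, "agent")
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      title = sprintf("%s agent (m = %d), %d replicates", agent$kind, agent$m,
                      nrow(object)),
      x = metric, y = "replicates") +
    ggplot2::theme_minimal()
}

#' Plot an efficiency sweep over memory sizes
#'
#' Standard-error plot of mean coverage-after-hops or hops-to-coverage as a
#' function of memory size.
#'
#' @param object An `rw_sweep` tibble from [coverage_at_hops()] or
#'   [hops_to_coverage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rw_sweep <- function(object, ...) {
  metric <- attr(object, "metric")
  ylab <- if (identical(metric, "coverage_at_hops")) {
    sprintf("mean coverage after %d hops (%%)", attr(object, "hops"))
  } else {
    sprintf("mean hops to %.0f%% coverage", attr(object, "target"))
  }
  ggplot2::ggplot(object, ggplot2::aes(x = m, y = mean, colour = kind)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - se, ymax = mean + se)) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey50") +
    ggplot2::labs(x = "memory size m", y = ylab, colour = "agent") +
    ggplot2::theme_minimal()
}

#' Draw visit ratios on the room layout
#'
#' Scatter of the room positions, one facet per floor, with point size
#' scaled by the visit ratio y and colour marking rooms outside the neutral
#' band (above `upper` red, below `lower` green, like a scaled layout map).
#'
#' @param ratio A ratio tibble with columns `room_id`, `y` (e.g. from
#'   [visit_ratio()]).
#' @param g The [env_graph].
#' @param upper,lower Highlight thresholds.
#' @return A ggplot.
#' @export
plot_visit_ratio <- function(ratio, g, upper = 1.05, lower = 0.95) {
  hl <- highlight_rooms(ratio, upper = upper, lower = lower)
  hl <- rename(hl[, c("room_id", "y", "highlight")], ratio_y = y)
  df <- dplyr::left_join(hl, rename(g$rooms, room_id = id), by = "room_id")
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$ratio_y, colour = highlight)) +
    ggplot2::facet_wrap(~floor, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(
      values = c(high = "red3", low = "green4", neutral = "grey40"),
      na.value = "grey80") +
    ggplot2::labs(size = "visit ratio y", x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
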