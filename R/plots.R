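# ggplot2 views of the main result types. These mirror the standard figures
# of trajectory-based emotion analyses: a path through v-a space colored by
# narrative time, the home-base ellipse, density/discordance arcs with a
# smooth trend overlay.

#' Plot a home-base ellipse
#'
#' @param object A `home_base_ellipse`.
#' @param trajectory Optional trajectory tibble (`t`, `v`, `a`) to draw
#'   under the ellipse, colored by narrative time.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.home_base_ellipse <- function(object, trajectory = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(trajectory)) {
    p <- p + ggplot2::geom_path(
      data = trajectory,
      ggplot2::aes(x = .data$v, y = .data$a, colour = .data$t),
      linewidth = 0.3
    ) +
      ggplot2::scale_colour_viridis_c(name = "narrative time")
  }
  p +
    ggplot2::geom_path(data = ellipse_boundary(object),
                       ggplot2::aes(x = .data$v, y = .data$a),
                       linetype = "dashed") +
    ggplot2::annotate("point", x = object$center[1], y = object$center[2],
                      shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "valence", y = "arousal",
                  title = sprintf("%.0f%% home base", 100 * object$confidence)) +
    ggplot2::theme_minimal()
}

#' Plot a trend curve with its data
#'
#' @param object A `ued_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ued_trend <- function(object, ...) {
  pts <- tibble::tibble(t = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_line(data = evaluate_trend(object),
                       ggplot2::aes(x = .data$t, y = .data$fitted),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "normalized narrative time", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot a speaker's valence-arousal trajectory
#'
#' @param traj A trajectory tibble from [rolling_trajectory()] (one speaker).
#' @param home Optional `home_base_ellipse` to overlay.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, home = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$v, y = .data$a,
                                          colour = .data$t)) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_colour_viridis_c(name = "narrative time") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "valence", y = "arousal") +
    ggplot2::theme_minimal()
  if (!is.null(home)) {
    p <- p + ggplot2::geom_path(data = ellipse_boundary(home),
                                ggplot2::aes(x = .data$v, y = .data$a),
                                inherit.aes = FALSE, linetype = "dashed")
  }
  p
}

#' Plot a discordance series
#'
#' @param disc A tibble from [discordance_series()] (or the pooled pipeline
#'   output with columns `t`, `distance`).
#' @param trend Optional `ued_trend` to overlay.
#' @return A ggplot object.
#' @export
plot_discordance <- function(disc, trend = NULL) {
  p <- ggplot2::ggplot(disc, ggplot2::aes(x = .data$t, y = .data$distance)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "normalized narrative time",
                  y = "discordance (v-a distance)") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    p <- p + ggplot2::geom_line(data = evaluate_trend(trend),
                                ggplot2::aes(x = .data$t, y = .data$fitted),
                                colour = "firebrick", linewidth = 0.8)
  }
  p
}
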