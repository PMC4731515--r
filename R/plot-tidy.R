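# ggplot2 visualisations and broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kymograph
#'
#' Distance along the line (vertical) against time (horizontal);
#' moving particles appear as sloped ridges whose slope is their speed.
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tidyr::crossing(i = seq_along(object$distance),
                        j = seq_along(object$times))
  df$value <- object$values[cbind(df$i, df$j)]
  df$distance <- object$distance[df$i]
  df$time <- object$times[df$j]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$distance,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "distance along line (um)") +
    ggplot2::theme_minimal()
}

#' Plot trajectories
#'
#' @param tracks Track tibble.
#' @param colour_by Column mapped to colour (default track identity).
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks, colour_by = "track_id") {
  tr <- tibble::as_tibble(tracks)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   group = .data$track_id,
                                   colour = factor(.data[[colour_by]]))) +
    ggplot2::geom_path(alpha = 0.8, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot a speed profile with stop/go phases
#'
#' @param profile Tibble (t, speed) from [speed_profile()].
#' @param phases Optional phase tibble from [segment_stop_go()].
#' @return A ggplot.
#' @export
plot_speed_profile <- function(profile, phases = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$t, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "speed (um/s)") +
    ggplot2::theme_minimal()
  if (!is.null(phases) && nrow(phases)) {
    p <- p + ggplot2::geom_rect(
      data = phases[phases$phase == "stop", , drop = FALSE],
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "red")
  }
  p
}

#' Plot a size distribution
#'
#' @param object A `size_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "diameter (nm)", y = "count") +
    ggplot2::theme_minimal()
}

#' @export
tidy.size_distribution <- function(x, ...) x$histogram

#' @export
glance.size_distribution <- function(x, ...) x$summary

#' @export
tidy.growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(rate_um_min = x$rate_um_min,
                 r.squared = summary(x$fit)$r.squared,
                 n = x$n, duration_s = x$duration_s)
}

#' @export
glance.endodance_report <- function(x, ...) x$summaries
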