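#' Plot daily flight time against the daily VeDBA sum
#'
#' @param records Tibble with `daily_vedba_sum` and `daily_flight_time_h`.
#' @return A ggplot with the OLS line.
#' @export
plot_flight_vedba <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$daily_vedba_sum,
    y = .data$daily_flight_time_h)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
      colour = "firebrick") +
    ggplot2::labs(x = "Daily sum of VeDBA", y = "Daily flight time (h)") +
    ggplot2::theme_minimal()
}

#' Plot the hourly distribution of interaction events
#'
#' @param diel Output of [diel_interaction_counts()].
#' @return A ggplot; night hours (when flagged) are shaded.
#' @export
plot_diel_interactions <- function(diel) {
  p <- ggplot2::ggplot(diel, ggplot2::aes(x = .data$hour, y = .data$n))
  if (!all(is.na(diel$n_night))) {
    night_hours <- diel$hour[!is.na(diel$n_night) & diel$n > 0 &
      diel$n_night >= diel$n / 2]
    shade <- diel$hour[diel$hour %in% night_hours]
    if (length(shade) > 0) {
      p <- p + ggplot2::annotate("rect", xmin = shade - 0.5,
        xmax = shade + 0.5, ymin = -Inf, ymax = Inf, alpha = 0.15)
    }
  }
  p + ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(0, 23, 3)) +
    ggplot2::labs(x = "Local hour (UTC+2)", y = "Interaction events") +
    ggplot2::theme_minimal()
}

#' Plot bird trips and vessel positions on a simple lat/lon canvas
#'
#' @param trips Nested trip tibble from [segment_trips()].
#' @param vms Optional gridded vessel track for context.
#' @param colony Optional colony coordinates.
#' @return A ggplot.
#' @export
plot_trips <- function(trips, vms = NULL, colony = NULL) {
  paths <- trips |>
    dplyr::mutate(.trip = .data$trip_id) |>
    tidyr::unnest("fixes", names_sep = "_")
  p <- ggplot2::ggplot()
  if (!is.null(vms)) {
    p <- p + ggplot2::geom_point(data = vms,
      ggplot2::aes(x = .data$lon, y = .data$lat), shape = 17,
      colour = "goldenrod3", alpha = 0.3, size = 1)
  }
  p <- p + ggplot2::geom_path(data = paths,
    ggplot2::aes(x = .data$fixes_lon, y = .data$fixes_lat,
      group = .data$.trip, colour = .data$bird_id), alpha = 0.7)
  if (!is.null(colony)) {
    p <- p + ggplot2::annotate("point", x = colony[["lon"]],
      y = colony[["lat"]], shape = 8, size = 3)
  }
  p + ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Bird") +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
}
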