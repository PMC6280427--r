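#' Segment bird tracks into central-place foraging trips
#'
#' A trip opens at the first fix beyond the colony departure radius and
#' closes at the first subsequent fix back inside. The bounding inside
#' fixes (last before departure, first after return) are included so trip
#' length integrals start and end at the colony. Excursions with fewer
#' than `min_sea_fixes` at-sea fixes are treated as GPS jitter and
#' discarded. Trips lasting up to 3 days are categorised `short`, the
#' stratum used for the group comparisons; longer trips are `long`.
#'
#' @param fixes Tibble `bird_id`, `t`, `lat`, `lon`, time-ordered per bird.
#' @param colony Named vector or list with `lat` and `lon`.
#' @param departure_radius_km Colony radius delimiting trips (km).
#' @param min_sea_fixes Minimum number of at-sea fixes for a real trip.
#' @param short_max_days Upper duration bound of the short category (days).
#' @return Nested tibble: `bird_id`, `trip_id`, `start`, `end`,
#'   `duration_days`, `category`, `complete`, `n_sea_fixes`, `fixes`
#'   (list column of the trip's fixes including boundary fixes).
#' @export
segment_trips <- function(fixes, colony, departure_radius_km = 2,
                          min_sea_fixes = 3, short_max_days = 3) {
  stopifnot(all(c("bird_id", "t", "lat", "lon") %in% names(fixes)))
  fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$t)
      if (any(diff(as.numeric(g$t)) <= 0)) {
        abort("fix timestamps must be strictly increasing per bird")
      }
      out <- haversine_km(g$lat, g$lon, colony[["lat"]],
        colony[["lon"]]) > departure_radius_km
      if (!any(out)) return(empty_trips())
      r <- rle(out)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      trips <- purrr::map_dfr(seq_along(runs), function(k) {
        i <- runs[k]
        sea <- starts[i]:ends[i]
        if (length(sea) < min_sea_fixes) return(NULL)
        pre <- if (starts[i] > 1) starts[i] - 1L else integer(0)
        post <- if (ends[i] < nrow(g)) ends[i] + 1L else integer(0)
        idx <- c(pre, sea, post)
        trip <- g[idx, ]
        tibble::tibble(
          start = trip$t[1], end = trip$t[nrow(trip)],
          complete = length(pre) == 1 && length(post) == 1,
          n_sea_fixes = length(sea),
          fixes = list(trip))
      })
      if (nrow(trips) == 0) return(empty_trips())
      trips |>
        dplyr::mutate(
          trip_id = paste0(key$bird_id[1], "_T",
            sprintf("%02d", dplyr::row_number())),
          duration_days = as.numeric(.data$end - .data$start, units = "days"),
          category = ifelse(.data$duration_days <= short_max_days,
            "short", "long")) |>
        dplyr::select("trip_id", "start", "end", "duration_days",
          "category", "complete", "n_sea_fixes", "fixes")
    }) |>
    dplyr::ungroup()
}

empty_trips <- function() {
  tibble::tibble(trip_id = character(), start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"), duration_days = numeric(),
    category = character(), complete = logical(), n_sea_fixes = integer(),
    fixes = list())
}

#' Per-trip movement metrics and interaction status
#'
#' Trip length is the summed great-circle distance between consecutive
#' fixes; the maximum linear distance is the farthest fix from the colony.
#' When interaction events are supplied, each trip gets its interaction
#' count and the INT factor used in the group comparisons
#' (`INT_YES` when at least one event falls inside the trip).
#'
#' @param trips Output of [segment_trips()].
#' @param colony Named vector or list with `lat` and `lon`.
#' @param events Optional interaction-event tibble with `bird_id` and
#'   `t_start`.
#' @return `trips` without the list column, plus `trip_length_km`,
#'   `max_colony_distance_km`, `n_interactions`, `int_flag`.
#' @export
trip_metrics <- function(trips, colony, events = NULL) {
  met <- purrr::map_dfr(trips$fixes, function(f) {
    d_col <- haversine_km(f$lat, f$lon, colony[["lat"]], colony[["lon"]])
    len <- if (nrow(f) < 2) 0 else sum(haversine_km(
      head(f$lat, -1), head(f$lon, -1), tail(f$lat, -1), tail(f$lon, -1)))
    tibble::tibble(trip_length_km = len, max_colony_distance_km = max(d_col))
  })
  out <- dplyr::bind_cols(dplyr::select(trips, -"fixes"), met)
  n_int <- integer(nrow(out))
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(out))) {
      n_int[i] <- sum(events$bird_id == out$bird_id[i] &
        events$t_start >= out$start[i] & events$t_start <= out$end[i])
    }
  }
  dplyr::mutate(out, n_interactions = n_int,
    int_flag = ifelse(n_int >= 1, "INT_YES", "INT_NO"))
}

#' Write the trip table CSV
#'
#' @param trip_table Output of [trip_metrics()].
#' @param path File path.
#' @export
write_trip_table <- function(trip_table, path) {
  trip_table |>
    dplyr::mutate(start = format_iso8601(.data$start),
      end = format_iso8601(.data$end)) |>
    readr::write_csv(path)
  invisible(path)
}
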