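#' Read and write the bird GPS CSV dialect
#'
#' Columns: `bird_id,timestamp_iso8601,lat,lon`. Timestamps are parsed as
#' UTC and fixes are returned ordered by bird and time.
#'
#' @param path File path.
#' @return A tibble with columns `bird_id`, `t` (`POSIXct` UTC), `lat`, `lon`.
#' @export
read_bird_gps <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      timestamp_iso8601 = readr::col_datetime(),
      lat = readr::col_double(),
      lon = readr::col_double()
    ))
  check_coords(x$lat, x$lon)
  x |>
    dplyr::transmute(bird_id = .data$bird_id,
      t = lubridate::with_tz(.data$timestamp_iso8601, "UTC"),
      lat = .data$lat, lon = .data$lon) |>
    dplyr::arrange(.data$bird_id, .data$t)
}

#' @rdname read_bird_gps
#' @param fixes Tibble with `bird_id`, `t`, `lat`, `lon`.
#' @export
write_bird_gps <- function(fixes, path) {
  fixes |>
    dplyr::transmute(bird_id = .data$bird_id,
      timestamp_iso8601 = format_iso8601(.data$t),
      lat = .data$lat, lon = .data$lon) |>
    readr::write_csv(path)
  invisible(path)
}

#' Read and write the vessel ping CSV dialect
#'
#' Columns:
#' `vessel_id,timestamp_iso8601,lat,lon,speed_kn,heading_deg,gear,activity`.
#'
#' @param path File path.
#' @return A tibble with columns `vessel_id`, `t` (`POSIXct` UTC), `lat`,
#'   `lon`, `speed_kn`, `heading_deg`, `gear`, `activity`.
#' @export
read_vessel_pings <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      vessel_id = readr::col_character(),
      timestamp_iso8601 = readr::col_datetime(),
      lat = readr::col_double(),
      lon = readr::col_double(),
      speed_kn = readr::col_double(),
      heading_deg = readr::col_double(),
      gear = readr::col_character(),
      activity = readr::col_character()
    ))
  check_coords(x$lat, x$lon)
  if (any(x$speed_kn < 0, na.rm = TRUE)) abort("speed_kn must be >= 0")
  x |>
    dplyr::transmute(vessel_id = .data$vessel_id,
      t = lubridate::with_tz(.data$timestamp_iso8601, "UTC"),
      lat = .data$lat, lon = .data$lon,
      speed_kn = .data$speed_kn,
      heading_deg = .data$heading_deg %% 360,
      gear = .data$gear, activity = .data$activity) |>
    dplyr::arrange(.data$vessel_id, .data$t)
}

#' @rdname read_vessel_pings
#' @param pings Tibble in the vessel ping layout.
#' @export
write_vessel_pings <- function(pings, path) {
  pings |>
    dplyr::transmute(vessel_id = .data$vessel_id,
      timestamp_iso8601 = format_iso8601(.data$t),
      lat = .data$lat, lon = .data$lon,
      speed_kn = .data$speed_kn, heading_deg = .data$heading_deg,
      gear = .data$gear, activity = .data$activity) |>
    readr::write_csv(path)
  invisible(path)
}

#' Read and write accelerometer CSV (`timestamp_iso8601,ax_g,ay_g,az_g`)
#'
#' @param path File path.
#' @param bird_id Identifier attached to the stream (the file format itself
#'   is single-bird).
#' @return A tibble with `bird_id`, `t` (`POSIXct` UTC, fractional seconds),
#'   `ax`, `ay`, `az` in g.
#' @export
read_accel <- function(path, bird_id = "bird") {
  x <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      timestamp_iso8601 = readr::col_datetime(),
      ax_g = readr::col_double(),
      ay_g = readr::col_double(),
      az_g = readr::col_double()
    ))
  tibble::tibble(bird_id = bird_id,
    t = lubridate::with_tz(x$timestamp_iso8601, "UTC"),
    ax = x$ax_g, ay = x$ay_g, az = x$az_g)
}

#' @rdname read_accel
#' @param acc Tibble with `t`, `ax`, `ay`, `az`.
#' @export
write_accel <- function(acc, path) {
  acc |>
    dplyr::transmute(timestamp_iso8601 = format_iso8601(.data$t, digits = 2),
      ax_g = .data$ax, ay_g = .data$ay, az_g = .data$az) |>
    readr::write_csv(path)
  invisible(path)
}

#' Write an ethogram segment table (`bird_id,start,end,label`)
#'
#' @param segments Tibble with `bird_id`, `start`, `end`, `label`.
#' @param path File path.
#' @export
write_ethogram <- function(segments, path) {
  segments |>
    dplyr::transmute(bird_id = .data$bird_id,
      start = format_iso8601(.data$start),
      end = format_iso8601(.data$end),
      label = .data$label) |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname write_ethogram
#' @export
read_ethogram <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      bird_id = readr::col_character(),
      start = readr::col_datetime(),
      end = readr::col_datetime(),
      label = readr::col_character()
    )) |>
    dplyr::mutate(start = lubridate::with_tz(.data$start, "UTC"),
      end = lubridate::with_tz(.data$end, "UTC"))
}

#' Export tracks as GeoJSON LineStrings
#'
#' One LineString feature per group (e.g. per bird trip or per vessel).
#'
#' @param track Tibble with `lat`, `lon` and a grouping column.
#' @param path Output file path.
#' @param id_col Name of the grouping column (default the first column).
#' @export
write_track_geojson <- function(track, path, id_col = names(track)[1]) {
  feats <- track |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::group_map(function(g, key) {
      list(type = "Feature",
        properties = stats::setNames(list(key[[1]][1]), id_col),
        geometry = list(type = "LineString",
          coordinates = unname(purrr::map2(g$lon, g$lat, c))))
    })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

format_iso8601 <- function(t, digits = 0) {
  if (digits > 0) {
    format(t, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  } else {
    format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
}
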