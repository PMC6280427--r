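#' Interpolate native VMS pings onto a common time grid
#'
#' Native VMS pings arrive every 1-2 h at vessel-specific times. To compare
#' all vessels (and birds) at the same instants, positions are linearly
#' interpolated in lat/lon onto a global grid aligned to the UTC hour
#' (minutes divisible by `grid_step_min`), as if every vessel transmitted
#' simultaneously. Grid-point speed is the great-circle distance of the
#' bracketing native segment over its duration; heading is the segment's
#' initial bearing. Gaps longer than `max_gap_h` are never interpolated
#' across (the track is split there).
#'
#' @param pings Tibble in the vessel-ping layout (`vessel_id`, `t`, `lat`,
#'   `lon`, `speed_kn`, `heading_deg`, `gear`, `activity`).
#' @param grid_step_min Grid step in minutes (default 10).
#' @param max_gap_h Longest native gap (hours) that may be bridged.
#' @return Tibble in the same layout on the regular grid, with
#'   `activity = "unknown"` (use [classify_activity()] to fill it).
#' @export
interpolate_pings <- function(pings, grid_step_min = 10, max_gap_h = 4) {
  step <- grid_step_min * 60
  pings |>
    dplyr::group_by(.data$vessel_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$t)
      if (nrow(g) < 2) {
        warn(paste0("vessel ", key$vessel_id[1],
          ": single-ping trip skipped"))
        return(g[0, setdiff(names(g), "vessel_id")])
      }
      tn <- as.numeric(g$t)
      seg <- cumsum(c(0, diff(tn) > max_gap_h * 3600))
      purrr::map_dfr(split(seq_len(nrow(g)), seg), function(ii) {
        if (length(ii) < 2) return(NULL)
        h <- g[ii, ]
        hn <- tn[ii]
        grid <- seq(ceiling(hn[1] / step) * step,
          floor(hn[length(hn)] / step) * step, by = step)
        if (length(grid) == 0) return(NULL)
        lat <- approx(hn, h$lat, xout = grid)$y
        lon <- approx(hn, h$lon, xout = grid)$y
        nseg <- length(hn) - 1
        d_km <- haversine_km(head(h$lat, -1), head(h$lon, -1),
          tail(h$lat, -1), tail(h$lon, -1))
        sp_kn <- d_km / (diff(hn) / 3600) / 1.852
        hd <- geosphere::bearing(
          cbind(head(h$lon, -1), head(h$lat, -1)),
          cbind(tail(h$lon, -1), tail(h$lat, -1))) %% 360
        j <- pmin(pmax(findInterval(grid, hn), 1L), nseg)
        tibble::tibble(
          t = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
          lat = lat, lon = lon,
          speed_kn = sp_kn[j],
          heading_deg = hd[j],
          gear = h$gear[1],
          activity = "unknown")
      })
    }) |>
    dplyr::ungroup()
}

#' Default fishing-speed bands per gear
#'
#' Gear classes operate in characteristic speed ranges while fishing;
#' pings with speed inside the band are classified as fishing, outside as
#' steaming. Bands are in knots and fully configurable.
#'
#' @return Tibble with `gear`, `lo_kn`, `hi_kn`.
#' @export
default_fishing_bands <- function() {
  tibble::tribble(
    ~gear,         ~lo_kn, ~hi_kn,
    "trawl",          1.0,    4.5,
    "purse_seine",    0.0,    2.5,
    "longline",       3.0,    7.0)
}

#' Classify vessel activity by speed filters
#'
#' @param track Vessel-ping tibble with `speed_kn` and `gear` filled.
#' @param bands Tibble `gear`, `lo_kn`, `hi_kn`; gears without a band get
#'   `activity = "unknown"`.
#' @return The track with `activity` in
#'   `c("fishing", "steaming", "unknown")`.
#' @export
classify_activity <- function(track, bands = default_fishing_bands()) {
  if (anyNA(track$speed_kn)) abort("speeds must be present to classify activity")
  track |>
    dplyr::left_join(bands, by = "gear") |>
    dplyr::mutate(activity = dplyr::case_when(
      is.na(.data$lo_kn) ~ "unknown",
      .data$speed_kn >= .data$lo_kn & .data$speed_kn <= .data$hi_kn ~ "fishing",
      TRUE ~ "steaming")) |>
    dplyr::select(-"lo_kn", -"hi_kn")
}
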