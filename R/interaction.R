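#' Attach sitting-time fractions to GPS fixes
#'
#' For each fix, the fraction of SIT-labelled seconds in the 5-min interval
#' following the fix (fix-aligned, forward, matching the GPS sampling
#' semantics).
#'
#' @param fixes Bird fix tibble (`bird_id`, `t`, ...).
#' @param seconds Per-second label tibble (`bird_id`, `sec`, `label`),
#'   e.g. from [ethogram()].
#' @param window_s Width of the forward window in seconds.
#' @return `fixes` with a `sit_fraction` column (`NA` where no labelled
#'   seconds fall in the window).
#' @export
add_sit_fraction <- function(fixes, seconds, window_s = 300) {
  fixes |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$t)
      s <- seconds[seconds$bird_id == key$bird_id[1], ]
      g$sit_fraction <- NA_real_
      if (nrow(s) > 0) {
        tn <- as.numeric(g$t)
        sn <- as.numeric(s$sec)
        idx <- findInterval(sn, tn)
        ok <- idx >= 1 & sn < tn[pmax(idx, 1L)] + window_s
        if (any(ok)) {
          frac <- tapply(s$label[ok] == "SIT", idx[ok], mean)
          g$sit_fraction[as.integer(names(frac))] <- as.numeric(frac)
        }
      }
      g
    }) |>
    dplyr::ungroup()
}

#' Join bird fixes with gridded vessel pings
#'
#' For each bird fix at time t, the single vessel ping in the half-open
#' temporal window [t - window, t + window) is selected per vessel (with a
#' 10-min vessel grid and a 5-min window this ping is unique by
#' construction; should two grid pings ever fall in the window, the nearer
#' in time wins, ties going to the earlier). Pairs farther apart than
#' `radius_km` are dropped.
#'
#' @param fixes Bird fixes (`bird_id`, `t`, `lat`, `lon`, optionally
#'   `sit_fraction`).
#' @param vms Gridded vessel track tibble from [interpolate_pings()].
#' @param window_min Half-width of the temporal window in minutes.
#' @param radius_km Maximum bird-vessel distance retained.
#' @return Tibble `bird_id`, `vessel_id`, `t` (bird fix time), `t_vessel`,
#'   `distance_km`, `gear`, `activity`, and `sit_fraction` when present on
#'   the fixes.
#' @export
match_pairs <- function(fixes, vms, window_min = 5, radius_km = 50) {
  if (nrow(vms) == 0 || nrow(fixes) == 0) return(empty_pairs())
  step <- median(unlist(tapply(as.numeric(vms$t), vms$vessel_id,
    function(x) diff(sort(unique(x))))), na.rm = TRUE)
  if (!is.finite(step) || step <= 0) abort("cannot infer vessel grid step")
  w <- window_min * 60
  tn <- as.numeric(fixes$t)
  cand1 <- ceiling((tn - w) / step) * step
  cand2 <- cand1 + step
  use2 <- cand2 < tn + w &
    (abs(cand2 - tn) < abs(cand1 - tn)) # tie -> earlier
  tg <- ifelse(use2, cand2, cand1)
  tg[tg >= tn + w] <- NA
  fx <- dplyr::mutate(fixes, .tg = tg)
  fx <- fx[!is.na(fx$.tg), ]
  if (nrow(fx) == 0) return(empty_pairs())
  vm <- dplyr::mutate(vms, .tg = as.numeric(.data$t))
  pairs <- dplyr::inner_join(
    dplyr::rename(fx, t_bird = "t", lat_b = "lat", lon_b = "lon"),
    dplyr::rename(vm, t_vessel = "t", lat_v = "lat", lon_v = "lon"),
    by = ".tg", relationship = "many-to-many")
  if (nrow(pairs) == 0) return(empty_pairs())
  pairs$distance_km <- haversine_km(pairs$lat_b, pairs$lon_b,
    pairs$lat_v, pairs$lon_v)
  keep <- c("bird_id", "vessel_id", "t_bird", "t_vessel", "distance_km",
    "gear", "activity", intersect("sit_fraction", names(pairs)))
  pairs |>
    dplyr::filter(.data$distance_km <= radius_km) |>
    dplyr::select(dplyr::all_of(keep)) |>
    dplyr::rename(t = "t_bird") |>
    dplyr::arrange(.data$bird_id, .data$vessel_id, .data$t)
}

empty_pairs <- function() {
  tibble::tibble(bird_id = character(), vessel_id = character(),
    t = as.POSIXct(character(), tz = "UTC"),
    t_vessel = as.POSIXct(character(), tz = "UTC"),
    distance_km = numeric(), gear = character(), activity = character())
}

#' Detect approach events from bird-vessel distance series
#'
#' Within each bird-vessel pair series, maximal runs of temporally
#' consecutive fixes with decreasing distance are extracted. A run
#' qualifies as an approach event when it has at least two fixes
#' (> 10 min), the cumulative decrease reaches `min_drop_km`, and it
#' starts within `max_start_km` (the maximum attraction distance); runs
#' beginning farther out are trimmed to their first fix inside
#' `max_start_km` rather than discarded.
#'
#' @param pairs Output of [match_pairs()].
#' @param min_drop_km Minimum distance decrease (km); default 0.5.
#' @param max_start_km Maximum attraction distance (km); default 30.
#' @param rule `"cumulative"` (strictly decreasing at every step with
#'   cumulative drop >= `min_drop_km`, the stricter reading) or
#'   `"per_step"` (every single step must drop by >= `min_drop_km`).
#' @param fix_step_min Nominal bird GPS interval (minutes); fixes further
#'   apart than `gap_factor` times this are not consecutive.
#' @param gap_factor Tolerance factor on the fix interval.
#' @return Tibble `bird_id`, `vessel_id`, `t_start`, `t_end`, `n_fixes`,
#'   `start_distance_km`, `min_distance_km`, `fixes` (list column with the
#'   run's `t` and `distance_km`).
#' @export
detect_approaches <- function(pairs, min_drop_km = 0.5, max_start_km = 30,
                              rule = c("cumulative", "per_step"),
                              fix_step_min = 5, gap_factor = 1.5) {
  rule <- match.arg(rule)
  if (nrow(pairs) == 0) return(empty_approaches())
  max_dt <- gap_factor * fix_step_min * 60
  pairs |>
    dplyr::group_by(.data$bird_id, .data$vessel_id) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$t)
      n <- nrow(g)
      if (n < 2) return(empty_approaches()[, 3:8])
      dt <- diff(as.numeric(g$t))
      dd <- diff(g$distance_km)
      brk <- if (rule == "cumulative") dd >= 0 else dd > -min_drop_km
      run <- cumsum(c(0L, as.integer(brk | dt > max_dt)))
      out <- purrr::map_dfr(split(seq_len(n), run), function(ii) {
        d <- g$distance_km[ii]
        j <- which(d <= max_start_km)
        if (length(j) == 0) return(NULL)
        ii <- ii[j[1]:length(ii)]
        d <- g$distance_km[ii]
        if (length(ii) < 2 || d[1] - d[length(d)] < min_drop_km) return(NULL)
        tibble::tibble(
          t_start = g$t[ii[1]], t_end = g$t[ii[length(ii)]],
          n_fixes = length(ii),
          start_distance_km = d[1], min_distance_km = min(d),
          fixes = list(tibble::tibble(t = g$t[ii], distance_km = d)))
      })
      if (nrow(out) == 0) empty_approaches()[, 3:8] else out
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$bird_id, .data$t_start)
}

empty_approaches <- function() {
  tibble::tibble(bird_id = character(), vessel_id = character(),
    t_start = as.POSIXct(character(), tz = "UTC"),
    t_end = as.POSIXct(character(), tz = "UTC"),
    n_fixes = integer(), start_distance_km = numeric(),
    min_distance_km = numeric(), fixes = list())
}

#' Validate approach events against the interaction distance
#'
#' An approach becomes an interaction event only when the bird was observed
#' inside the interaction distance, i.e. its minimum distance does not
#' exceed the fitted breakpoint (closed boundary).
#'
#' @param approaches Output of [detect_approaches()].
#' @param fit A [fit_breakpoint()] object or a plain distance in km.
#' @return The validated subset with a `validated = TRUE` column.
#' @export
validate_interactions <- function(approaches, fit) {
  bp <- if (is.numeric(fit)) fit else fit$breakpoint_km
  approaches |>
    dplyr::filter(.data$min_distance_km <= bp) |>
    dplyr::mutate(validated = TRUE)
}

#' Hourly histogram of interaction events (local time)
#'
#' Events are binned by the local (UTC+2) hour of their first fix. When a
#' site is given, each event is also flagged night/day from the solar
#' elevation at its start.
#'
#' @param events Interaction-event tibble with `t_start`.
#' @param site Optional named vector/list with `lat`, `lon` for the night
#'   flag.
#' @return Tibble with `hour` (0-23), `n`, and `n_night` (NA without site).
#' @export
diel_interaction_counts <- function(events, site = NULL) {
  hours <- tibble::tibble(hour = 0:23)
  if (nrow(events) == 0) {
    return(dplyr::mutate(hours, n = 0L, n_night = NA_integer_))
  }
  ev <- tibble::tibble(
    hour = lubridate::hour(to_local_time(events$t_start)),
    night = if (is.null(site)) NA else
      night_mask(events$t_start, site[["lat"]], site[["lon"]]))
  counts <- ev |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(n = dplyr::n(),
      n_night = if (all(is.na(.data$night))) NA_integer_ else
        sum(.data$night), .groups = "drop")
  hours |>
    dplyr::left_join(counts, by = "hour") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Write the events CSV
#'
#' @param events Approach or interaction event tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  events |>
    dplyr::transmute(bird_id = .data$bird_id, vessel_id = .data$vessel_id,
      start = format_iso8601(.data$t_start),
      end = format_iso8601(.data$t_end),
      start_distance_km = .data$start_distance_km,
      min_distance_km = .data$min_distance_km,
      validated = if ("validated" %in% names(events)) .data$validated else FALSE) |>
    readr::write_csv(path)
  invisible(path)
}
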