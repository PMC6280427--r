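#' Run the full interaction-detection pipeline
#'
#' Orchestrates the stages end-to-end on in-memory tables: VMS
#' regularization and activity classification, bird-vessel pair matching,
#' approach detection, distance-profile construction, breakpoint
#' (interaction-distance) estimation, approach validation, trip
#' segmentation and metrics, and the group statistics.
#'
#' @param fixes Bird GPS fixes (`bird_id`, `t`, `lat`, `lon`).
#' @param pings Native vessel pings (vessel-ping layout).
#' @param sit_fixes `fixes` with a `sit_fraction` column (from
#'   [add_sit_fraction()] on a classified ethogram, or
#'   [truth_sit_fraction()] on simulated data).
#' @param colony Named vector/list with `lat`, `lon`.
#' @param params Named list of stage-parameter overrides:
#'   `grid_step_min`, `max_gap_h`, `window_min`, `radius_km`,
#'   `min_drop_km`, `max_start_km`, `bin_km`, `min_count`,
#'   `profile_max_km`, `n_boot`, `departure_radius_km`, `fishing_only`.
#' @param seed Seed for the bootstrap.
#' @return List with `vms`, `pairs`, `approaches`, `profile`, `fit`,
#'   `events` (validated interactions), `trips`, `trip_table`, `diel`.
#' @export
run_pipeline <- function(fixes, pings, sit_fixes, colony,
                         params = list(), seed = 1) {
  p <- utils::modifyList(list(
    grid_step_min = 10, max_gap_h = 4, window_min = 5, radius_km = 50,
    min_drop_km = 0.5, max_start_km = 30, bin_km = 0.25,
    min_count = NULL, profile_max_km = 5, n_boot = 1000,
    departure_radius_km = 2, fishing_only = FALSE), params)

  vms <- interpolate_pings(pings, grid_step_min = p$grid_step_min,
    max_gap_h = p$max_gap_h)
  vms <- classify_activity(vms)
  vms_used <- if (p$fishing_only) {
    dplyr::filter(vms, .data$activity == "fishing")
  } else {
    vms
  }

  # interactions are a foraging-trip phenomenon: only at-sea fixes
  # (outside the colony departure radius) enter the pairing
  at_sea <- haversine_km(sit_fixes$lat, sit_fixes$lon,
    colony[["lat"]], colony[["lon"]]) > p$departure_radius_km
  pairs <- match_pairs(sit_fixes[at_sea, ], vms_used,
    window_min = p$window_min, radius_km = p$radius_km)
  approaches <- detect_approaches(pairs, min_drop_km = p$min_drop_km,
    max_start_km = p$max_start_km)
  profile <- build_distance_profile(pairs, bin_km = p$bin_km,
    min_count = p$min_count, max_km = p$profile_max_km)
  fit <- fit_breakpoint(profile, n_boot = p$n_boot, seed = seed)
  events <- validate_interactions(approaches, fit)

  trips <- segment_trips(fixes, colony,
    departure_radius_km = p$departure_radius_km)
  trip_table <- trip_metrics(trips, colony, events)
  diel <- diel_interaction_counts(events, site = colony)

  list(vms = vms, pairs = pairs, approaches = approaches,
    profile = profile, fit = fit, events = events, trips = trips,
    trip_table = trip_table, diel = diel, params = p)
}

#' Score detected events against planted ground truth
#'
#' Sensitivity is measured against the *planted* attendance bouts the
#' generator scheduled (each reaches inside the true interaction
#' distance). A detected event counts as false only when it corresponds to
#' no real sub-threshold encounter at all: detections overlapping an
#' unplanted episode in which the bird genuinely came inside the true
#' interaction distance (`truth_runs`) are correct detections, not false
#' alarms. Matching is by bird, vessel and time overlap with `slack_s`
#' tolerance.
#'
#' @param events Validated events from the pipeline.
#' @param planted_events Scheduled bouts from [simulate_bird_tracks()].
#' @param truth_runs All true sub-threshold encounter episodes derived
#'   from the emitted trajectories (same source); `NULL` to treat every
#'   unmatched detection as false.
#' @param bird_days Number of tracked bird-days in the dataset.
#' @param slack_s Overlap slack in seconds.
#' @return One-row tibble: `n_planted`, `n_detected`, `n_matched`,
#'   `n_false`, `sensitivity`, `false_per_bird_day`.
#' @export
score_detection <- function(events, planted_events, truth_runs = NULL,
                            bird_days, slack_s = 600) {
  match_tab <- function(tab) {
    hit_tab <- logical(nrow(tab))
    hit_ev <- logical(nrow(events))
    for (i in seq_len(nrow(tab))) {
      j <- which(events$bird_id == tab$bird_id[i] &
        events$vessel_id == tab$vessel_id[i] &
        as.numeric(events$t_start) <= as.numeric(tab$t_end[i]) + slack_s &
        as.numeric(tab$t_start[i]) <= as.numeric(events$t_end) + slack_s)
      if (length(j) > 0) {
        hit_tab[i] <- TRUE
        hit_ev[j] <- TRUE
      }
    }
    list(tab = hit_tab, ev = hit_ev)
  }
  mp <- match_tab(planted_events)
  excused <- mp$ev
  if (!is.null(truth_runs) && nrow(truth_runs) > 0) {
    excused <- excused | match_tab(truth_runs)$ev
  }
  tibble::tibble(
    n_planted = nrow(planted_events), n_detected = nrow(events),
    n_matched = sum(mp$tab), n_false = sum(!excused),
    sensitivity = if (nrow(planted_events) == 0) NA_real_ else
      mean(mp$tab),
    false_per_bird_day = sum(!excused) / bird_days)
}
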