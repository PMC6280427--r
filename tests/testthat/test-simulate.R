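test_that("the generator is fully reproducible under a fixed seed", {
  cfg <- sim_config(n_birds = 2, n_vessels = 3, days = 1, seed = 19)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$vessels_native, b$vessels_native)
  expect_identical(a$planted_events, b$planted_events)
})

test_that("without scavengers no interactions are planted", {
  cfg <- sim_config(n_birds = 3, days = 1, frac_scavengers = 0, seed = 6)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$planted_events), 0)
  expect_true(all(ds$plan$behaviour != "FOLLOW"))
})

test_that("every planted bout reaches inside the true interaction distance", {
  cfg <- sim_config(n_birds = 6, days = 2, seed = 29)
  ds <- simulate_dataset(cfg)
  expect_gt(nrow(ds$planted_events), 0)
  expect_true(all(ds$planted_events$min_distance_km <=
    cfg$true_interaction_km))
})

test_that("the fleet draws the configured gear mix and fishing speeds", {
  cfg <- sim_config(n_vessels = 250, n_birds = 0, days = 1, seed = 37)
  vs <- simulate_vessel_tracks(cfg)
  gears <- dplyr::distinct(vs$truth, vessel_id, gear)
  p_trawl <- mean(gears$gear == "trawl")
  # binomial tolerance around the 76% trawler share
  expect_lt(abs(p_trawl - 0.76), 3 * sqrt(0.76 * 0.24 / 250))
  # pings emitted during fishing legs stay inside the configured band
  bands <- default_fishing_bands()
  f <- vs$truth |>
    dplyr::filter(activity == "fishing") |>
    dplyr::inner_join(bands, by = "gear")
  expect_gte(mean(f$speed_kn >= f$lo_kn & f$speed_kn <= f$hi_kn), 0.95)
})

test_that("zero-duration simulations are empty", {
  cfg <- sim_config(days = 0, seed = 1)
  vs <- simulate_vessel_tracks(cfg)
  expect_equal(nrow(vs$native), 0)
})

test_that("trip ground truth is consistent with GPS-derived trips", {
  cfg <- sim_config(n_birds = 4, days = 2, seed = 47)
  ds <- simulate_dataset(cfg)
  trips <- trip_metrics(segment_trips(ds$fixes, cfg$colony), cfg$colony)
  # match each derived trip to an overlapping truth trip, compare extremes
  step_km <- cfg$flight_speed_ms * cfg$gps_step_min * 60 / 1000
  matched <- 0
  for (i in seq_len(nrow(trips))) {
    cand <- ds$truth_trips[ds$truth_trips$bird_id == trips$bird_id[i] &
      ds$truth_trips$start <= trips$end[i] &
      ds$truth_trips$end >= trips$start[i], ]
    if (nrow(cand) == 1) {
      matched <- matched + 1
      expect_lt(abs(cand$max_colony_distance_km -
        trips$max_colony_distance_km[i]), step_km + 0.1)
      expect_lt(abs(cand$path_length_km - trips$trip_length_km[i]),
        0.05 * cand$path_length_km + 2 * step_km)
    }
  }
  expect_gt(matched, 0)
})

test_that("synthetic sitting and gliding close the loop with the classifier", {
  cfg <- sim_config(seed = 53)
  t0 <- t_utc("2023-06-15 08:00:00")
  mk_plan <- function(behaviour) tibble::tibble(bird_id = "B01",
    t = t0 + 0:11 * 300, behaviour = behaviour)
  still <- tibble::tibble(bird_id = "B01", t = t0 + c(0, 3600),
    lat = toy_colony[["lat"]], lon = toy_colony[["lon"]])

  sit <- synthesize_accel(mk_plan("SIT"), cfg)
  vs <- vedba_per_second(compute_vedba(sit$acc))
  vs$speed_ms <- gps_speed_per_second(still, vs$sec)
  expect_gte(mean(classify_sitting(vs)$sit), 0.95)

  glide_plan <- mk_plan("FLIGHT")
  gl <- synthesize_accel(glide_plan, cfg)
  glide_secs <- gl$labels$sec[gl$labels$label == "GLIDE"]
  vg <- vedba_per_second(compute_vedba(gl$acc))
  vg$speed_ms <- gps_speed_per_second(still, vg$sec)
  cg <- classify_sitting(vg)
  expect_lt(mean(cg$sit[cg$sec %in% glide_secs]), 0.05)
})

test_that("flapping windows carry the planted wingbeat frequency", {
  cfg <- sim_config(seed = 59)
  plan <- tibble::tibble(bird_id = "B01",
    t = t_utc("2023-06-15 08:00:00") + 0:5 * 300, behaviour = "FLIGHT")
  syn <- synthesize_accel(plan, cfg)
  flap_sec <- syn$labels$sec[syn$labels$label == "FLAP"][10]
  w <- syn$acc[syn$acc$t >= flap_sec & syn$acc$t < flap_sec + 1, ]
  amp <- abs(fft(abs(w$az) - mean(abs(w$az))))[2:13] * 2 / 25
  expect_equal(which.max(amp), cfg$wingbeat_hz, tolerance = 0.5)
})

test_that("emitted datasets are byte-identical across runs and readable", {
  cfg <- sim_config(n_birds = 2, n_vessels = 3, days = 1, seed = 61)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1, accel_hours = 1)
  emit_dataset(cfg, d2, accel_hours = 1)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
      readLines(file.path(d2, f)), label = f)
  }
  fixes <- read_bird_gps(file.path(d1, "bird_gps.csv"))
  expect_equal(nrow(fixes), nrow(simulate_dataset(cfg)$fixes))
  pings <- read_vessel_pings(file.path(d1, "vessel_pings.csv"))
  expect_true(all(c("speed_kn", "gear") %in% names(pings)))
  truth <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_true(all(c("planted_events", "truth_runs", "trips", "plan") %in%
    names(truth)))
})
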