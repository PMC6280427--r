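test_that("a track leaving the colony radius twice yields two trips", {
  d <- c(0, 0, 5, 10, 15, 10, 5, 0, 0, 6, 12, 18, 12, 6, 0, 0)
  trk <- toy_track(d)
  trips <- segment_trips(trk, toy_colony)
  expect_equal(nrow(trips), 2)
  expect_true(all(trips$complete))
  # boundary fixes included: first and last fix of each trip at the colony
  f1 <- trips$fixes[[1]]
  expect_lt(haversine_km(f1$lat[1], f1$lon[1], toy_colony[["lat"]],
    toy_colony[["lon"]]), 0.01)
})

test_that("tracks that never leave the radius yield no trips", {
  trk <- toy_track(rep(c(0, 0.5, 1), 4))
  expect_equal(nrow(segment_trips(trk, toy_colony)), 0)
})

test_that("trips are categorised short up to three days", {
  mk <- function(n_steps) {
    toy_track(c(0, rep(10, n_steps), 0), step_s = 3600 * 6)
  }
  short <- segment_trips(mk(9), toy_colony)   # 2.5 days
  long <- segment_trips(mk(16), toy_colony)   # 4 days
  expect_equal(short$category, "short")
  expect_equal(long$category, "long")
})

test_that("trip metrics match hand geometry on collinear fixes", {
  # colony at first fix; 3 fixes 10 km apart along a meridian
  trk <- toy_track(c(0, 10, 20), bearing = 0)
  trips <- tibble::tibble(bird_id = "B1", trip_id = "B1_T01",
    start = trk$t[1], end = trk$t[3], duration_days = 0.01,
    category = "short", complete = TRUE, n_sea_fixes = 2L,
    fixes = list(trk))
  m <- trip_metrics(trips, toy_colony)
  expect_equal(m$trip_length_km, 20, tolerance = 1e-6)
  expect_equal(m$max_colony_distance_km, 20, tolerance = 1e-6)
  expect_equal(m$int_flag, "INT_NO")
})

test_that("trip length is invariant under time reversal", {
  set.seed(9)
  trk <- toy_track(cumsum(runif(12, 0, 4)))
  rev_trk <- dplyr::mutate(trk[nrow(trk):1, ], t = sort(t))
  mk <- function(f) tibble::tibble(bird_id = "B1", trip_id = "T",
    start = f$t[1], end = f$t[nrow(f)], duration_days = 1,
    category = "short", complete = TRUE, n_sea_fixes = 10L,
    fixes = list(f))
  expect_equal(trip_metrics(mk(trk), toy_colony)$trip_length_km,
    trip_metrics(mk(rev_trk), toy_colony)$trip_length_km)
})

test_that("interaction counts and INT flags attach to the right trips", {
  d <- c(0, 5, 10, 5, 0, 0, 5, 10, 5, 0)
  trk <- toy_track(d)
  trips <- segment_trips(trk, toy_colony)
  events <- tibble::tibble(bird_id = "B1", vessel_id = "V1",
    t_start = trips$start[1] + 600, t_end = trips$start[1] + 1200)
  m <- trip_metrics(trips, toy_colony, events)
  expect_equal(m$n_interactions, c(1L, 0L))
  expect_equal(m$int_flag, c("INT_YES", "INT_NO"))
  expect_true(all(m$max_colony_distance_km <= m$trip_length_km))
})

test_that("trip durations never exceed the tracking span", {
  cfg <- sim_config(n_birds = 3, days = 2, seed = 13)
  ds <- simulate_dataset(cfg)
  trips <- segment_trips(ds$fixes, cfg$colony)
  per_bird <- trips |>
    dplyr::group_by(bird_id) |>
    dplyr::summarise(tot = sum(duration_days))
  expect_true(all(per_bird$tot <= cfg$days))
})
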