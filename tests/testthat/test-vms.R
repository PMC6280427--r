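test_that("ping interpolation hits the grid and is exact on linear paths", {
  native <- tibble::tibble(vessel_id = "V1",
    t = t_utc("2023-06-15 06:03:00") + c(0, 3600),
    lat = c(0, 0.1), lon = c(12, 12), speed_kn = NA_real_,
    heading_deg = 0, gear = "trawl", activity = "unknown")
  out <- interpolate_pings(native)
  expect_true(all(lubridate::minute(out$t) %% 10 == 0))
  # linear-in-time path: interpolation reproduces it exactly
  frac <- as.numeric(out$t - native$t[1], units = "secs") / 3600
  expect_equal(out$lat, 0.1 * frac, tolerance = 1e-12)
  # pings on the grid at t = 0 and 1 h: the 30-min point is the midpoint
  native2 <- dplyr::mutate(native, t = t_utc("2023-06-15 06:00:00") +
    c(0, 3600))
  out2 <- interpolate_pings(native2)
  expect_equal(out2$lat[out2$t == t_utc("2023-06-15 06:30:00")], 0.05)
})

test_that("stationary vessels interpolate in place with zero speed", {
  native <- tibble::tibble(vessel_id = "V1",
    t = t_utc("2023-06-15 06:00:00") + c(0, 5400, 10800),
    lat = 35.5, lon = 13, speed_kn = NA_real_, heading_deg = 0,
    gear = "trawl", activity = "unknown")
  out <- interpolate_pings(native)
  expect_true(all(out$lat == 35.5 & out$lon == 13))
  expect_true(all(out$speed_kn == 0))
})

test_that("gaps beyond max_gap_h split the track and singletons warn", {
  native <- tibble::tibble(vessel_id = "V1",
    t = t_utc("2023-06-15 00:00:00") + c(0, 3600, 6 * 3600, 7 * 3600),
    lat = c(35, 35.1, 36, 36.1), lon = 13, speed_kn = NA_real_,
    heading_deg = 0, gear = "trawl", activity = "unknown")
  out <- interpolate_pings(native, max_gap_h = 4)
  # nothing interpolated inside the 5 h gap
  in_gap <- out$t > native$t[2] & out$t < native$t[3]
  expect_equal(sum(in_gap), 0)
  single <- native[1, ]
  expect_warning(res <- interpolate_pings(single), "single-ping")
  expect_equal(nrow(res), 0)
})

test_that("interpolated positions track a simulated trawler within 1.5 km", {
  cfg <- sim_config(n_vessels = 6, days = 2, seed = 21)
  vs <- simulate_vessel_tracks(cfg)
  trawl_ids <- unique(vs$truth$vessel_id[vs$truth$gear == "trawl"])
  expect_true(length(trawl_ids) > 0)
  vms <- interpolate_pings(vs$native)
  cmp <- dplyr::inner_join(
    vms[vms$vessel_id %in% trawl_ids, ],
    vs$truth[vs$truth$vessel_id %in% trawl_ids, ],
    by = c("vessel_id", "t"), suffix = c("_i", "_t"))
  err <- haversine_km(cmp$lat_i, cmp$lon_i, cmp$lat_t, cmp$lon_t)
  expect_lt(mean(err), 1.5)
})

test_that("speed filters classify fishing vs steaming by gear band", {
  trk <- tibble::tibble(vessel_id = "V1",
    t = t_utc("2023-06-15 06:00:00") + 0:3 * 600,
    lat = 35.5, lon = 13,
    speed_kn = c(3, 10, 1, 5),
    heading_deg = 0,
    gear = c("trawl", "trawl", "other", "longline"),
    activity = "unknown")
  out <- classify_activity(trk)
  expect_equal(out$activity, c("fishing", "steaming", "unknown", "fishing"))
})
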