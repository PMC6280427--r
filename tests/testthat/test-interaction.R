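test_that("each fix pairs with the unique grid ping in its half-open window", {
  vms <- toy_vessel_grid(rep(10, 13))
  # fix at 10:02-style offset: 06:02, window [05:57, 06:07) -> 06:00 ping
  fix <- tibble::tibble(bird_id = "B1", t = t_utc("2023-06-15 06:02:00"),
    lat = toy_colony[["lat"]], lon = toy_colony[["lon"]])
  pr <- match_pairs(fix, vms)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$t_vessel, t_utc("2023-06-15 06:00:00"))
  # exactly one ping per vessel for every fix on the nominal cadence
  trk <- toy_track(rep(1, 20))
  pr2 <- match_pairs(trk, vms)
  expect_true(all(dplyr::count(pr2, t)$n == 1))
})

test_that("pairs beyond the 50 km radius are dropped", {
  vms <- toy_vessel_grid(rep(60, 13))
  trk <- toy_track(rep(0, 10))
  expect_equal(nrow(match_pairs(trk, vms)), 0)
})

test_that("approach detection follows the decrease rules", {
  mk_pairs <- function(d) tibble::tibble(bird_id = "B1", vessel_id = "V1",
    t = t_utc("2023-06-15 06:00:00") + (seq_along(d) - 1) * 300,
    distance_km = d, sit_fraction = 0)
  # hand trace: 20, 15, 10, 12 -> one event over fixes 1-3
  ev <- detect_approaches(mk_pairs(c(20, 15, 10, 12)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_distance_km, 20)
  expect_equal(ev$min_distance_km, 10)
  expect_equal(ev$n_fixes, 3L)
  # cumulative decrease below 500 m is no event
  expect_equal(nrow(detect_approaches(mk_pairs(c(10.0, 9.8, 9.7)))), 0)
  # runs from beyond 30 km are trimmed to the attraction distance
  ev2 <- detect_approaches(mk_pairs(c(35, 28, 20)))
  expect_equal(ev2$start_distance_km, 28)
  # per-step rule needs every single step to drop by the threshold
  ev3 <- detect_approaches(mk_pairs(c(20, 19.9, 15)), rule = "per_step")
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$start_distance_km, 19.9)
})

test_that("approach detection ignores vessel ordering and interleaving", {
  d1 <- c(20, 15, 10); d2 <- c(8, 7.9, 7.85)
  tt <- t_utc("2023-06-15 06:00:00") + 0:2 * 300
  pr <- dplyr::bind_rows(
    tibble::tibble(bird_id = "B1", vessel_id = "V1", t = tt,
      distance_km = d1, sit_fraction = 0),
    tibble::tibble(bird_id = "B1", vessel_id = "V2", t = tt,
      distance_km = d2, sit_fraction = 0))
  ev_a <- detect_approaches(pr)
  ev_b <- detect_approaches(pr[sample.int(nrow(pr)), ])
  expect_equal(nrow(ev_a), 1) # V2's 0.15 km drop does not qualify
  expect_equal(ev_a$vessel_id, "V1")
  expect_equal(dplyr::select(ev_a, -fixes), dplyr::select(ev_b, -fixes))
})

test_that("distance profile bins use the half-open convention", {
  pr <- tibble::tibble(distance_km = c(0.1, 0.25, 0.3, 1.0, 1.1),
    sit_fraction = c(1, 1, 0, 0, 1))
  prof <- build_distance_profile(pr, min_count = 1)
  expect_equal(prof$bin_lo_km, c(0, 0.25, 1.0))
  # the pair at exactly 0.25 km falls into the second bin
  expect_equal(prof$n_pairs, c(1L, 2L, 2L))
  expect_equal(prof$mean_sit_pct, c(100, 50, 50))
})

test_that("binned sitting means track the planted binomial probabilities", {
  prs <- simulate_profile_pairs(8000, true_km = 1.28, seed = 31)
  prof <- build_distance_profile(prs)
  inside <- prof$mean_sit_pct[prof$bin_hi_km <= 1.25]
  outside <- prof$mean_sit_pct[prof$bin_lo_km >= 1.5]
  se <- 100 * sqrt(0.8 * 0.2 / min(prof$n_pairs))
  expect_true(all(abs(inside - 80) < 3 * se))
  expect_true(all(abs(outside - 20) < 3 * se))
})

test_that("the split minimiser equals exhaustive brute force with lm", {
  # independent oracle: fit both sides with lm() at every candidate split
  brute <- function(x, y) {
    n <- length(x)
    rss <- sapply(2:(n - 2), function(k) {
      sum(stats::resid(lm(y[1:k] ~ x[1:k]))^2) +
        sum(stats::resid(lm(y[(k + 1):n] ~ x[(k + 1):n]))^2)
    })
    x[which.min(rss) + 1] # ties go to the smaller breakpoint
  }
  set.seed(17)
  for (r in 1:25) {
    x <- (1:12) * 0.25 - 0.125
    y <- runif(12, 0, 100)
    prof <- tibble::tibble(bin_mid_km = x, mean_sit_pct = y)
    f <- fit_breakpoint(prof, n_boot = 10, seed = 1)
    expect_equal(f$split_x, brute(x, y))
  }
})

test_that("noiseless two-segment data recovers the planted knee", {
  x <- seq(0.125, 7.875, by = 0.25)
  y <- ifelse(x < 1.28, 80, 20)
  prof <- tibble::tibble(bin_mid_km = x, mean_sit_pct = y)
  f <- fit_breakpoint(prof, n_boot = 100, seed = 2)
  expect_lt(abs(f$breakpoint_km - 1.28), 0.25)
  expect_true(f$ci95[["lo"]] <= f$breakpoint_km)
  expect_true(f$ci95[["hi"]] >= f$breakpoint_km)
})

test_that("a flat profile is a degenerate fit", {
  prof <- tibble::tibble(bin_mid_km = seq(0.125, 2, by = 0.25),
    mean_sit_pct = 50)
  expect_error(fit_breakpoint(prof, n_boot = 10), "degenerate")
})

test_that("validation keeps only events reaching the interaction distance", {
  ev <- tibble::tibble(bird_id = "B1", vessel_id = "V1",
    t_start = t_utc("2023-06-15 06:00:00"), t_end = t_utc("2023-06-15 06:30:00"),
    n_fixes = 3L, start_distance_km = 10,
    min_distance_km = c(1.0, 2.0, 1.28), fixes = list(NULL, NULL, NULL))
  got <- validate_interactions(ev, 1.28)
  # closed boundary: exactly-at-threshold passes
  expect_equal(got$min_distance_km, c(1.0, 1.28))
  expect_true(all(got$validated))
})

test_that("diel histogram bins events by local hour and conserves counts", {
  # local (UTC+2) 06:10, 06:40, 19:05 -> UTC 04:10, 04:40, 17:05
  ev <- tibble::tibble(
    t_start = t_utc(c("2023-06-15 04:10:00", "2023-06-15 04:40:00",
      "2023-06-15 17:05:00")))
  d <- diel_interaction_counts(ev)
  expect_equal(d$n[d$hour == 6], 2L)
  expect_equal(d$n[d$hour == 19], 1L)
  expect_equal(sum(d$n), 3L)
  empty <- diel_interaction_counts(ev[0, ])
  expect_true(all(empty$n == 0))
})

test_that("tidy, glance and autoplot work on a breakpoint fit", {
  prs <- simulate_profile_pairs(5000, seed = 8)
  f <- fit_breakpoint(build_distance_profile(prs), n_boot = 50, seed = 1)
  td <- tidy(f)
  expect_true(all(c("breakpoint_km", "slope_left") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$breakpoint_km, f$breakpoint_km)
  expect_s3_class(autoplot(f), "ggplot")
})
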