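test_that("flapping windows are recovered from alternating signal blocks", {
  set.seed(1)
  rate <- 25
  tt <- seq(0, 600 - 1 / rate, by = 1 / rate)
  block <- floor(tt / 30) %% 2 == 0
  acc <- tibble::tibble(t = t_utc("2023-06-15") + tt,
    az = 1 + ifelse(block, sin(2 * pi * 4 * tt), 0) +
      rnorm(length(tt), 0, 0.04))
  fl <- detect_flapping(acc)
  truth <- block[seq(1, length(tt), by = rate)]
  expect_gte(mean(fl$flap == truth), 0.95)

  # cluster order invariance: doubling the amplitude changes nothing
  acc2 <- dplyr::mutate(acc, az = 1 +
    ifelse(block, 2 * sin(2 * pi * 4 * tt), 0) + rnorm(length(tt), 0, 0.04))
  expect_identical(detect_flapping(acc2)$flap, fl$flap)
})

test_that("degenerate signals yield no flapping windows", {
  set.seed(2)
  tt <- seq(0, 120 - 1 / 25, by = 1 / 25)
  noise <- tibble::tibble(t = t_utc("2023-06-15") + tt,
    az = 1 + rnorm(length(tt), 0, 0.05))
  expect_equal(sum(detect_flapping(noise)$flap), 0)
  flat <- dplyr::mutate(noise, az = 1)
  expect_equal(sum(detect_flapping(flat)$flap), 0)
})

test_that("gliding fills short gaps bounded by flapping, never the edges", {
  base <- tibble::tibble(sec = t_utc("2023-06-15") + 0:99,
    flap = FALSE, sit = FALSE)
  base$flap[11:30] <- TRUE   # flap run
  base$flap[41:60] <- TRUE   # 10 s gap -> glide
  base$flap[97:100] <- TRUE  # 36 s gap -> too long
  lab <- infer_gliding(base, max_gap_s = 30)$label
  expect_true(all(lab[31:40] == "GLIDE"))
  expect_true(all(lab[61:96] == "OTHER"))
  expect_true(all(lab[1:10] == "OTHER")) # leading gap never glide
})

test_that("ethogram segments partition the labelled span without overlap", {
  cfg <- sim_config(n_birds = 1, days = 1, seed = 3)
  ds <- simulate_dataset(cfg)
  sub <- ds$plan[ds$plan$t < cfg$start + 3 * 3600, ]
  syn <- synthesize_accel(sub, cfg)
  eth <- ethogram(syn$acc, ds$fixes[ds$fixes$bird_id == "B01", ])
  seg <- eth$segments
  expect_true(all(seg$start < seg$end))
  # segments tile the span: each starts where the previous ended
  expect_equal(as.numeric(seg$start[-1]), as.numeric(seg$end[-nrow(seg)]))
  expect_equal(sum(as.numeric(seg$end - seg$start, units = "secs")),
    nrow(eth$seconds))
})

test_that("daily summaries add up flight time and interval VeDBA", {
  # one 6 h flight segment in a single local day
  segs <- tibble::tibble(bird_id = "b",
    start = t_utc("2023-06-15 04:00:00"),
    end = t_utc("2023-06-15 10:00:00"), label = "FLAP")
  secs <- tibble::tibble(bird_id = "b",
    sec = t_utc("2023-06-15 04:00:00") + 0:(6 * 3600 - 1),
    label = "FLAP", vedba_mean = 0.4)
  out <- daily_summaries(secs)
  expect_equal(out$daily_flight_time_h, 6)
  # constant per-interval mean c over k intervals sums to k * c
  expect_equal(out$daily_vedba_sum, 72 * 0.4)
})

test_that("a planted flight budget is recovered from the ethogram chain", {
  # plant 6.22 h of flight in one synthetic day and re-measure it
  cfg <- sim_config(n_birds = 1, days = 1, seed = 5)
  n_flight <- round(6.22 * 12)
  beh <- c(rep("COLONY", 24), rep("FLIGHT", n_flight),
    rep("SIT", 36), rep("COLONY", 288 - 60 - n_flight))
  plan <- tibble::tibble(bird_id = "B01",
    t = cfg$start + (seq_along(beh) - 1) * 300, behaviour = beh)
  syn <- synthesize_accel(plan, cfg)
  truth_day <- daily_summaries(dplyr::mutate(syn$labels, vedba_mean = 0))
  expect_equal(truth_day$daily_flight_time_h[1], n_flight / 12)

  pts <- vesselbird:::dest_point_km(35.8592, 12.8594, 90,
    cumsum(c(0, ifelse(beh[-1] == "FLIGHT", 3, 0))))
  fixes <- tibble::tibble(bird_id = "B01", t = plan$t,
    lat = pts[, 1], lon = pts[, 2])
  eth <- ethogram(syn$acc, fixes)
  got <- daily_summaries(eth)
  expect_equal(got$daily_flight_time_h[1], 6.22, tolerance = 0.1)
})
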