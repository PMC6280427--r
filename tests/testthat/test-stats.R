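test_that("flight-on-VeDBA regression is exact on a noiseless line", {
  rec <- tibble::tibble(daily_vedba_sum = seq(20, 60, by = 2),
    daily_flight_time_h = 0.1 * seq(20, 60, by = 2))
  f <- regress_flight_on_vedba(rec)
  g <- glance(f)
  expect_equal(g$slope, 0.1, tolerance = 1e-12)
  expect_equal(sum(stats::resid(f$lm)^2), 0, tolerance = 1e-20)
  # permutation invariance
  g2 <- glance(regress_flight_on_vedba(rec[sample.int(nrow(rec)), ]))
  expect_equal(g2$slope, g$slope)
  expect_error(regress_flight_on_vedba(
    dplyr::mutate(rec, daily_vedba_sum = 40)), "zero-variance")
})

test_that("regression slope lands within 3 SE of the generating slope", {
  set.seed(23)
  n <- 150
  x <- rnorm(n, 40, 10)
  rec <- tibble::tibble(daily_vedba_sum = x,
    daily_flight_time_h = 1 + 0.12 * x + rnorm(n, 0, 1))
  td <- tidy(regress_flight_on_vedba(rec))
  sl <- td[td$term == "daily_vedba_sum", ]
  expect_lt(abs(sl$estimate - 0.12), 3 * sl$std.error)
})

test_that("the mixed model reduces to ordinary regression when balanced", {
  # balanced within-bird design with no bird effect: GLS equals OLS
  set.seed(3)
  rec <- tidyr::expand_grid(bird_id = sprintf("B%02d", 1:10),
    int_flag = c("INT_NO", "INT_YES")) |>
    dplyr::mutate(sex = rep(c("M", "F"), each = 10),
      daily_flight_time_h = 5 + 0.9 * (int_flag == "INT_YES") +
        rnorm(20, 0, 0.5))
  lmm <- fit_lmm(rec, "daily_flight_time_h", transform = "none")
  ols <- lm(daily_flight_time_h ~ sex + int_flag, data = rec)
  expect_equal(unname(lmm$coefs$estimate), unname(stats::coef(ols)),
    tolerance = 1e-6)
})

test_that("a planted interaction contrast is recovered within 3 SE", {
  rec <- simulate_trip_records(seed = 41)
  f <- fit_lmm(rec, "daily_flight_time_h", transform = "none")
  row <- f$coefs[grepl("INT_YES", f$coefs$term), ]
  expect_lt(abs(row$estimate - 0.94), 3 * row$std.error)
  expect_equal(row$df2, nrow(rec) - nrow(f$coefs))
})

test_that("log transform engages for skewed positive responses", {
  rec <- simulate_trip_records(seed = 42)
  f <- fit_lmm(rec, "trip_length_km")
  expect_equal(f$transform, "log")
})

test_that("gear preference chi-square matches hand computation", {
  # observed (90, 10) vs availability (0.5, 0.5):
  # (90-50)^2/50 + (10-50)^2/50 = 64
  ev <- tibble::tibble(gear = c(rep("trawl", 90), rep("longline", 10)))
  fleet <- tibble::tibble(gear = c("trawl", "longline"),
    n_vessels = c(50L, 50L))
  got <- gear_preference_test(ev, fleet)
  expect_equal(got$statistic, 64)
  expect_equal(got$df, 1L)
  # doubling all counts doubles the statistic exactly
  got2 <- gear_preference_test(dplyr::bind_rows(ev, ev), fleet)
  expect_equal(got2$statistic, 128)
  # observed equal to availability gives zero
  ev0 <- tibble::tibble(gear = c(rep("trawl", 50), rep("longline", 50)))
  expect_equal(gear_preference_test(ev0, fleet)$statistic, 0)
})

test_that("sex-by-interaction chi-square matches the 2x2 closed form", {
  birds <- tibble::tibble(
    sex = rep(c("M", "F"), each = 10),
    int_flag = c(rep("INT_YES", 10), rep("INT_NO", 10)))
  got <- sex_interaction_test(birds)
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 20 * (10*10)^2 / 10^4 = 20
  expect_equal(got$statistic, 20)
  expect_equal(got$df, 1L)
  # swapping row labels changes nothing
  swapped <- dplyr::mutate(birds, sex = ifelse(sex == "M", "F", "M"))
  expect_equal(sex_interaction_test(swapped)$statistic, got$statistic)
  # balanced table gives zero
  bal <- tibble::tibble(sex = rep(c("M", "F"), 10),
    int_flag = rep(c("INT_YES", "INT_NO"), each = 10))
  expect_equal(sex_interaction_test(bal)$statistic, 0)
  expect_error(sex_interaction_test(birds[birds$sex == "M", ]), "degenerate")
})

test_that("summary tables reproduce fleet percentages and group spreads", {
  tabs <- summary_tables(simulate_trip_records(seed = 2),
    strait_fleet_counts())
  expect_equal(sum(tabs$gear_table$n_vessels), 414L)
  expect_equal(tabs$gear_table$pct[match(
    c("trawl", "purse_seine", "longline", "other"), tabs$gear_table$gear)],
    c(76, 11, 6, 7))
  # identical values have zero SD
  const <- tibble::tibble(bird_id = "b", trip_id = as.character(1:4),
    sex = "M", int_flag = "INT_NO", daily_flight_time_h = 5)
  ft <- summary_tables(const, strait_fleet_counts())$foraging_table
  expect_equal(ft$sd, 0)
})
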