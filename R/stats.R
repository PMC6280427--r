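#' Regress daily flight time on the daily sum of VeDBA
#'
#' Ordinary least squares of daily flight time (hours) on the daily VeDBA
#' sum, with the F test of the slope. A positive slope indicates that
#' flight is the energetically expensive behaviour.
#'
#' @param records Tibble with `daily_flight_time_h` and `daily_vedba_sum`.
#' @return Object of class `flight_vedba_fit` wrapping the `lm`;
#'   `tidy()`/`glance()` methods available.
#' @export
regress_flight_on_vedba <- function(records) {
  stopifnot(all(c("daily_flight_time_h", "daily_vedba_sum") %in%
    names(records)))
  if (nrow(records) < 3) abort("need at least 3 records")
  if (sd(records$daily_vedba_sum) == 0) {
    abort("zero-variance covariate: daily_vedba_sum is constant")
  }
  fit <- lm(daily_flight_time_h ~ daily_vedba_sum, data = records)
  structure(list(lm = fit, n = nrow(records)), class = "flight_vedba_fit")
}

#' @export
print.flight_vedba_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Daily flight time ~ daily VeDBA sum: slope %.4f h/unit, F(%d,%d) = %.1f, p = %.3g\n",
    g$slope, 1L, g$df2, g$statistic, g$p.value))
  invisible(x)
}

#' @method tidy flight_vedba_fit
#' @export
tidy.flight_vedba_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
    std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @method glance flight_vedba_fit
#' @export
glance.flight_vedba_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(slope = unname(stats::coef(x$lm)[2]),
    intercept = unname(stats::coef(x$lm)[1]),
    r.squared = s$r.squared,
    statistic = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
    p.value = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
    n = x$n)
}

#' Linear mixed model of a foraging response on sex and interaction status
#'
#' REML fit (via `nlme::lme`) with bird identity as random intercept. A
#' normality screen (Shapiro-Wilk on the residuals of the untransformed
#' ordinary fit, alpha = 0.05) decides a log transform when
#' `transform = "auto"` and the response is strictly positive. Should the
#' mixed fit fail (e.g. one trip per bird), the function falls back to
#' ordinary regression with a warning.
#'
#' F statistics are squared Wald t ratios for each fixed effect; the
#' denominator degrees of freedom follow the observations-minus-parameters
#' convention and are a reporting convention, not exact small-sample
#' inference.
#'
#' @param records Tibble with one row per trip(-day): the response column,
#'   `sex`, `int_flag`, `bird_id`.
#' @param response Name of the response column.
#' @param interaction Include the sex x INT interaction term?
#' @param transform `"auto"`, `"none"` or `"log"`.
#' @return Object of class `vb_lmm` with a coefficient table;
#'   `tidy()`/`glance()` methods available.
#' @export
fit_lmm <- function(records, response, interaction = FALSE,
                    transform = c("auto", "none", "log")) {
  transform <- match.arg(transform)
  stopifnot(all(c(response, "sex", "int_flag", "bird_id") %in%
    names(records)))
  records <- dplyr::mutate(records,
    sex = factor(.data$sex), int_flag = factor(.data$int_flag))
  rhs <- if (interaction) "sex * int_flag" else "sex + int_flag"
  y <- records[[response]]

  use_log <- transform == "log"
  if (transform == "auto" && all(y > 0)) {
    res0 <- stats::residuals(lm(stats::reformulate(rhs, "y"),
      data = dplyr::mutate(records, y = y)))
    sw <- tryCatch(shapiro.test(res0)$p.value, error = function(e) 1)
    use_log <- sw < 0.05
  }
  records$.y <- if (use_log) log(y) else y
  fml <- stats::reformulate(rhs, ".y")

  fallback <- FALSE
  fit <- tryCatch(
    nlme::lme(fml, random = ~ 1 | bird_id, data = records,
      method = "REML"),
    error = function(e) {
      warn(paste0("mixed model failed (", conditionMessage(e),
        "); falling back to ordinary regression"))
      fallback <<- TRUE
      lm(fml, data = records)
    })

  if (fallback) {
    ct <- summary(fit)$coefficients
    sig_b <- 0
    sig_e <- summary(fit)$sigma
  } else {
    ct <- summary(fit)$tTable[, c("Value", "Std.Error", "t-value",
      "p-value"), drop = FALSE]
    vc <- nlme::VarCorr(fit)
    sig_b <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    sig_e <- fit$sigma
  }
  n <- nrow(records)
  p <- nrow(ct)
  df2 <- n - p
  coefs <- tibble::tibble(term = rownames(ct),
    estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3]^2, df1 = 1L, df2 = df2,
    p.value = pf(ct[, 3]^2, 1, df2, lower.tail = FALSE))

  structure(list(response = response, transform = if (use_log) "log" else "none",
    coefs = coefs, sigma_bird = sig_b, sigma_resid = sig_e,
    n = n, n_birds = dplyr::n_distinct(records$bird_id),
    fallback = fallback, fit = fit), class = "vb_lmm")
}

#' @export
print.vb_lmm <- function(x, ...) {
  cat(sprintf("LMM: %s%s ~ fixed effects + (1 | bird), %s\n",
    if (x$transform == "log") "log " else "", x$response,
    if (x$fallback) "OLS fallback" else "REML"))
  cat(sprintf("  random intercept SD %.3f, residual SD %.3f, n = %d (%d birds)\n",
    x$sigma_bird, x$sigma_resid, x$n, x$n_birds))
  print(as.data.frame(x$coefs), digits = 4)
  invisible(x)
}

#' @method tidy vb_lmm
#' @export
tidy.vb_lmm <- function(x, ...) x$coefs

#' @method glance vb_lmm
#' @export
glance.vb_lmm <- function(x, ...) {
  tibble::tibble(response = x$response, transform = x$transform,
    sigma_bird = x$sigma_bird, sigma_resid = x$sigma_resid,
    n = x$n, n_birds = x$n_birds, fallback = x$fallback)
}

#' Gear preference chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed trawler versus
#' non-trawler interaction counts against the availability proportions in
#' the fleet.
#'
#' @param events Interaction events with `vessel_id` (and `gear` if the
#'   fleet table is not given per vessel).
#' @param fleet Either a vessel table with `vessel_id` and `gear` (one row
#'   per ping is fine; vessels are deduplicated) or a gear count table with
#'   `gear` and `n_vessels`.
#' @param correct Apply Yates continuity correction (off by default).
#' @return One-row tibble: `statistic`, `df`, `p.value`, observed and
#'   expected trawler shares, and `low_expected` flagging any expected
#'   count below 5.
#' @export
gear_preference_test <- function(events, fleet, correct = FALSE) {
  if (!"gear" %in% names(events)) {
    stopifnot(all(c("vessel_id", "gear") %in% names(fleet)))
    events <- dplyr::left_join(events,
      dplyr::distinct(fleet, .data$vessel_id, .data$gear), by = "vessel_id")
  }
  if (all(c("gear", "n_vessels") %in% names(fleet))) {
    avail <- fleet |> dplyr::group_by(trawl = .data$gear == "trawl") |>
      dplyr::summarise(n = sum(.data$n_vessels), .groups = "drop")
  } else {
    avail <- fleet |> dplyr::distinct(.data$vessel_id, .data$gear) |>
      dplyr::group_by(trawl = .data$gear == "trawl") |>
      dplyr::summarise(n = dplyr::n(), .groups = "drop")
  }
  if (nrow(avail) < 2) abort("need at least 2 gear classes in the fleet")
  p_trawl <- avail$n[avail$trawl] / sum(avail$n)
  obs <- c(trawl = sum(events$gear == "trawl"),
    other = sum(events$gear != "trawl"))
  expd <- sum(obs) * c(p_trawl, 1 - p_trawl)
  if (any(expd < 5)) warn("expected count below 5 in a cell")
  stat <- sum((abs(obs - expd) - if (correct) 0.5 else 0)^2 / expd)
  tibble::tibble(statistic = stat, df = 1L,
    p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
    obs_trawl_share = obs[["trawl"]] / sum(obs),
    expected_trawl_share = p_trawl,
    low_expected = any(expd < 5))
}

#' Sex-by-interaction chi-square test
#'
#' Pearson chi-square on the 2x2 table of bird sex against whether the
#' bird interacted at least once, without continuity correction by
#' default.
#'
#' @param birds Tibble with one row per bird: `sex` and `int_flag`.
#' @param correct Apply Yates continuity correction.
#' @return One-row tibble `statistic`, `df`, `p.value`.
#' @export
sex_interaction_test <- function(birds, correct = FALSE) {
  tab <- table(birds$sex, birds$int_flag)
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate 2x2 table: empty row or column")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  tibble::tibble(statistic = unname(ht$statistic),
    df = unname(ht$parameter), p.value = unname(ht$p.value))
}

#' Fleet composition and foraging-variable summary tables
#'
#' @param records Trip(-day) records with `int_flag` and any of the four
#'   foraging responses (`daily_vedba_sum`, `daily_flight_time_h`,
#'   `trip_length_km`, `max_colony_distance_km`).
#' @param fleet Gear count table (`gear`, `n_vessels`) or a vessel table
#'   with `vessel_id` and `gear`.
#' @return List with `gear_table` (counts and integer-rounded percentages)
#'   and `foraging_table` (mean and SD per response by INT group).
#' @export
summary_tables <- function(records, fleet) {
  if (!all(c("gear", "n_vessels") %in% names(fleet))) {
    fleet <- fleet |> dplyr::distinct(.data$vessel_id, .data$gear) |>
      dplyr::count(.data$gear, name = "n_vessels")
  }
  gear_table <- fleet |>
    dplyr::transmute(gear = .data$gear, n_vessels = .data$n_vessels,
      pct = round(100 * .data$n_vessels / sum(.data$n_vessels)))

  responses <- intersect(c("daily_vedba_sum", "daily_flight_time_h",
    "trip_length_km", "max_colony_distance_km"), names(records))
  foraging_table <- records |>
    tidyr::pivot_longer(dplyr::all_of(responses), names_to = "response") |>
    dplyr::group_by(.data$response, .data$int_flag) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE), n = dplyr::n(),
      .groups = "drop")
  list(gear_table = gear_table, foraging_table = foraging_table)
}

#' Fleet composition of the central Mediterranean study area
#'
#' Bundled example gear counts for the fishing fleet operating in the
#' Strait of Sicily during a shearwater chick-rearing season (June-August):
#' 315 bottom otter trawlers, 45 purse seiners, 25 longliners and 29
#' vessels with other gears.
#'
#' @return Tibble with `gear` and `n_vessels`.
#' @export
strait_fleet_counts <- function() {
  tibble::tibble(
    gear = c("trawl", "purse_seine", "longline", "other"),
    n_vessels = c(315L, 45L, 25L, 29L))
}
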