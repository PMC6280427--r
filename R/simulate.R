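#' Configuration for the synthetic study generator
#'
#' Bundles the conditions under which the synthetic bird and vessel data
#' are generated: a breeding colony on a small Mediterranean island, birds
#' sampled every 5 min by GPS, vessels reporting native VMS pings every
#' 1-2 h, a fraction of scavenging birds that divert to vessels, and a
#' known true interaction distance planted in the behaviour (sitting
#' probability `sit_prob_inside` within `true_interaction_km` of an
#' attended vessel, `sit_prob_outside` while milling around it farther
#' out).
#'
#' Fishing grounds occupy the sector of bearings 0-180 degrees from the
#' colony and natural foraging patches the opposite sector, so that close
#' bird-vessel encounters are (almost) only the planted ones and detection
#' sensitivity/false-alarm rates can be scored against ground truth.
#'
#' @param n_birds,n_vessels,days Study size.
#' @param colony Named vector `lat`, `lon`; default Linosa island.
#' @param start First day (UTC midnight) of the simulation.
#' @param frac_scavengers Fraction of birds that attend vessels.
#' @param true_interaction_km Planted interaction distance (km).
#' @param attraction_km Maximum attraction distance (km).
#' @param sit_prob_inside,sit_prob_outside Per-5-min sitting probability
#'   within the interaction distance / while milling beyond it.
#' @param mill_km Range (lo, hi) of milling distances from the attended
#'   vessel (km).
#' @param wingbeat_hz Flapping frequency for the accelerometer synthesis.
#' @param accel_noise_sd Accelerometer noise SD (g) outside sitting;
#'   sitting uses `sit_noise_sd` (wave-induced motion inside the
#'   0.1-1 g VeDBA band).
#' @param sit_noise_sd Per-axis dynamic noise SD (g) while on the water.
#' @param gps_step_min Bird GPS interval (minutes).
#' @param vms_native_step_min Mean native VMS ping interval (minutes).
#' @param flight_speed_ms Bird commuting/approach flight speed (m/s).
#' @param gear_mix Named gear probabilities for the fleet.
#' @param seed Master seed; every stream derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_birds = 6, n_vessels = 8, days = 3,
                       colony = c(lat = 35.8592, lon = 12.8594),
                       start = as.POSIXct("2023-06-15 00:00:00", tz = "UTC"),
                       frac_scavengers = 0.5,
                       true_interaction_km = 1.28, attraction_km = 30,
                       sit_prob_inside = 0.8, sit_prob_outside = 0.2,
                       mill_km = c(1.5, 4.75),
                       wingbeat_hz = 4, accel_noise_sd = 0.04,
                       sit_noise_sd = 0.25,
                       gps_step_min = 5, vms_native_step_min = 75,
                       flight_speed_ms = 10,
                       gear_mix = c(trawl = 0.76, purse_seine = 0.11,
                         longline = 0.06, other = 0.07),
                       seed = 1) {
  stopifnot(frac_scavengers >= 0, frac_scavengers <= 1,
    true_interaction_km < attraction_km,
    sit_prob_inside >= 0, sit_prob_inside <= 1,
    sit_prob_outside >= 0, sit_prob_outside <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate fishing-vessel tracks and native VMS pings
#'
#' Vessels alternate steaming legs (8-12 kn) with gear-specific fishing
#' legs (speed inside the gear's fishing band, quasi-linear hauls) around
#' an operating centre in the fishing sector. The true path is kept on a
#' 10-min grid; native pings are emitted at the native VMS cadence with
#' jitter, as in real fleets.
#'
#' @param cfg A [sim_config()].
#' @return List with `native` (vessel-ping tibble at native cadence,
#'   `activity` filled with the true leg type) and `truth` (the 10-min
#'   true track).
#' @export
simulate_vessel_tracks <- function(cfg) {
  if (cfg$days <= 0 || cfg$n_vessels <= 0) {
    return(list(native = empty_vessel_pings(), truth = empty_vessel_pings()))
  }
  step <- 600
  times <- seq(as.numeric(cfg$start), as.numeric(cfg$start) +
    cfg$days * 86400 - step, by = step)
  bands <- default_fishing_bands()
  # operating centres in the fishing sector, spaced >= 12 km apart so
  # grounds do not pile up on one spot (vessels stay on a 6 km leash)
  centres <- withr::with_seed(cfg$seed + 91L, {
    out <- matrix(NA_real_, cfg$n_vessels, 2)
    for (j in seq_len(cfg$n_vessels)) {
      for (try in 1:100) {
        cand <- dest_point_km(cfg$colony[["lat"]], cfg$colony[["lon"]],
          runif(1, 5, 175), runif(1, 30, 80))
        if (j == 1 || all(haversine_km(cand[1], cand[2],
          out[seq_len(j - 1), 1], out[seq_len(j - 1), 2]) >= 28)) break
      }
      out[j, ] <- cand
    }
    out
  })
  res <- list()
  for (j in seq_len(cfg$n_vessels)) {
    res[[j]] <- withr::with_seed(cfg$seed + 577L * j, {
      gear <- sample(names(cfg$gear_mix), 1, prob = cfg$gear_mix)
      band <- bands[bands$gear == gear, ]
      if (nrow(band) == 0) band <- tibble::tibble(lo_kn = 2, hi_kn = 4)
      centre <- centres[j, ]
      lat <- numeric(length(times)); lon <- numeric(length(times))
      spd <- numeric(length(times)); act <- character(length(times))
      pos <- centre
      heading <- runif(1, 0, 360)
      i <- 1L
      while (i <= length(times)) {
        fishing <- runif(1) < 0.85
        dur <- if (fishing) round(runif(1, 30, 48)) else round(runif(1, 4, 8))
        speed <- if (fishing) {
          runif(1, band$lo_kn + 0.2, band$hi_kn - 0.2)
        } else {
          runif(1, 8, 12)
        }
        # quasi-linear legs; between legs the vessel turns in a wide arc
        # (<= 10 degrees per 10-min step) rather than an instant corner,
        # keeping linear ping interpolation honest
        target_heading <- heading + sample(c(-1, 1), 1) * runif(1, 10, 35)
        for (s in seq_len(dur)) {
          if (i > length(times)) break
          lat[i] <- pos[1]; lon[i] <- pos[2]
          spd[i] <- speed
          act[i] <- if (fishing) "fishing" else "steaming"
          turn <- ((target_heading - heading + 540) %% 360) - 180
          max_turn <- if (fishing) 10 else 25
          heading <- heading + max(-max_turn, min(max_turn, turn))
          # enforce the ground leash: only genuinely outbound headings are
          # redirected, so home-bound vessels run straight instead of
          # orbiting the boundary with sustained (interp-hostile) curvature
          if (haversine_km(pos[1], pos[2], centre[1], centre[2]) > 10) {
            home <- bearing_deg(pos[1], pos[2], centre[1], centre[2])
            off <- abs(((target_heading - home + 540) %% 360) - 180)
            if (off > 60) target_heading <- home
          }
          # no fishing around the colony island itself
          if (haversine_km(pos[1], pos[2], cfg$colony[["lat"]],
              cfg$colony[["lon"]]) < 12) {
            target_heading <- bearing_deg(cfg$colony[["lat"]],
              cfg$colony[["lon"]], pos[1], pos[2])
          }
          pos <- dest_point_km(pos[1], pos[2], heading,
            speed * 1.852 * step / 3600)
          i <- i + 1L
        }
      }
      truth <- tibble::tibble(vessel_id = sprintf("V%02d", j),
        t = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
        lat = lat, lon = lon, speed_kn = spd,
        heading_deg = 0, gear = gear, activity = act)
      # native pings: jittered 1-2 h cadence sampled off the true track
      tn <- as.numeric(cfg$start) + runif(1, 0, 600)
      pick <- numeric(0)
      while (tn < max(times)) {
        pick <- c(pick, tn)
        tn <- tn + 60 * cfg$vms_native_step_min * runif(1, 0.8, 1.2)
      }
      idx <- pmax(1L, findInterval(pick, times))
      native <- truth[idx, ]
      native$t <- as.POSIXct(pick, origin = "1970-01-01", tz = "UTC")
      native$lat <- approx(times, lat, xout = pick, rule = 2)$y
      native$lon <- approx(times, lon, xout = pick, rule = 2)$y
      native$activity <- "unknown"
      list(native = native, truth = truth)
    })
  }
  list(native = purrr::map_dfr(res, "native"),
    truth = purrr::map_dfr(res, "truth"))
}

empty_vessel_pings <- function() {
  tibble::tibble(vessel_id = character(),
    t = as.POSIXct(character(), tz = "UTC"), lat = numeric(),
    lon = numeric(), speed_kn = numeric(), heading_deg = numeric(),
    gear = character(), activity = character())
}

# linear position lookup functions for each vessel's true track
vessel_interpolators <- function(truth) {
  split(truth, truth$vessel_id) |>
    purrr::map(function(v) {
      tn <- as.numeric(v$t)
      list(lat = stats::approxfun(tn, v$lat, rule = 2),
        lon = stats::approxfun(tn, v$lon, rule = 2))
    })
}

#' Simulate central-place foraging bird tracks with planted interactions
#'
#' Each bird performs one foraging trip per day. Non-scavengers commute to
#' a natural patch in the patch sector and sit there; scavengers head for
#' the fishing grounds, mill around an attended vessel at 1.5-8 km,
#' approach it in direct flight and follow it inside the true interaction
#' distance for 45-120 min (sitting on the water behind it), sometimes
#' twice, before returning to the colony.
#'
#' Ground truth comes in two layers. `planted_events` are the scheduled
#' attendance bouts (one per goto-mill-approach-follow cycle, each
#' reaching inside the true interaction distance by construction) -- the
#' reference for detection sensitivity. `truth_runs` are derived from the
#' emitted trajectories: for every bird-vessel pair, each maximal run of
#' fixes within the attraction distance whose minimum true distance falls
#' inside `true_interaction_km` (scheduled follows and chance encounters
#' alike) -- the reference for judging whether a detection corresponds to
#' any real encounter.
#'
#' @param cfg A [sim_config()].
#' @param vessels Output of [simulate_vessel_tracks()]; `NULL` simulates
#'   a fleet internally.
#' @return List with `fixes` (bird GPS tibble), `plan` (per-fix behaviour:
#'   SIT / FLIGHT / FOLLOW / COLONY), `planted_events`, `truth_runs`,
#'   `truth_trips`, and `vessels`.
#' @export
simulate_bird_tracks <- function(cfg, vessels = NULL) {
  if (is.null(vessels)) vessels <- simulate_vessel_tracks(cfg)
  vi <- vessel_interpolators(vessels$truth)
  step <- cfg$gps_step_min * 60
  dstar <- cfg$true_interaction_km
  n_scav <- round(cfg$frac_scavengers * cfg$n_birds)
  gear_of <- dplyr::distinct(vessels$truth, .data$vessel_id, .data$gear)
  trawlers <- gear_of$vessel_id[gear_of$gear == "trawl"]

  birds <- purrr::map(seq_len(cfg$n_birds), function(b) {
    withr::with_seed(cfg$seed + 101L * b, {
      scav <- b <= n_scav
      times <- seq(as.numeric(cfg$start), as.numeric(cfg$start) +
        cfg$days * 86400 - step, by = step)
      lat <- numeric(length(times)); lon <- numeric(length(times))
      beh <- character(length(times))
      pos <- c(cfg$colony[["lat"]], cfg$colony[["lon"]])

      day_of <- floor((times - times[1]) / 86400)
      agenda <- list(depart_at = Inf, phases = character(0))
      mode <- "colony"
      target <- NULL; remaining <- 0; cur_day <- -1
      follow_d <- 0.5 * dstar; mill_d <- mean(cfg$mill_km)
      patch <- NULL
      bouts <- list(); bout_start <- NA_real_; bout_min <- Inf
      was_sitting <- FALSE

      fly_toward <- function(pos, tgt, speed_ms) {
        d <- haversine_km(pos[1], pos[2], tgt[1], tgt[2])
        stp <- speed_ms * step / 1000
        if (d <= stp) return(c(tgt[1], tgt[2]))
        br <- bearing_deg(pos[1], pos[2], tgt[1], tgt[2]) + rnorm(1, 0, 4)
        p <- dest_point_km(pos[1], pos[2], br, stp)
        c(p[1], p[2])
      }
      vessel_pos <- function(v, tn) c(vi[[v]]$lat(tn), vi[[v]]$lon(tn))

      for (i in seq_along(times)) {
        tn <- times[i]
        # birds preferentially attend trawlers (high discard producers)
        pick_target <- function(current) {
          pool <- if (length(trawlers) > 0 && runif(1) < 0.87) trawlers
            else names(vi)
          if (length(pool) > 1 && !is.null(current)) {
            pool <- setdiff(pool, current)
          }
          pool[sample.int(length(pool), 1)]
        }
        enter_phase <- function(m) {
          if (m == "goto_vessel") {
            target <<- pick_target(target)
            bout_start <<- tn
            bout_min <<- Inf
          }
          if (m == "mill") {
            remaining <<- round(runif(1, 1.5, 3) * 12)
            mill_d <<- runif(1, cfg$mill_km[1], cfg$mill_km[2])
          }
          if (m == "approach") follow_d <<- runif(1, 0.1, 0.95) * dstar
          if (m == "follow") {
            remaining <<- round(runif(1, 60, 150) / cfg$gps_step_min)
          }
          if (m == "forage") remaining <<- round(runif(1, 3, 6) * 12)
          m
        }
        advance <- function() {
          agenda$phases <<- agenda$phases[-1]
          if (length(agenda$phases) == 0) "colony" else
            enter_phase(agenda$phases[1])
        }

        # a new day's agenda is laid out only once the bird is back at the
        # colony with the previous agenda finished (trips may run past
        # midnight); departure 03:30-05:30 UTC or as soon as possible
        if (mode == "colony" && length(agenda$phases) == 0 &&
            day_of[i] != cur_day) {
          cur_day <- day_of[i]
          day_start <- times[1] + cur_day * 86400
          depart <- max(day_start + 3.5 * 3600 +
            round(runif(1, 0, 2 * 3600) / step) * step, tn)
          if (scav) {
            n_follow <- sample(1:2, 1, prob = c(0.7, 0.3))
            agenda <- list(depart_at = depart,
              phases = c(rep(c("goto_vessel", "mill", "approach", "follow"),
                n_follow), "return"))
          } else {
            patch <- dest_point_km(cfg$colony[["lat"]], cfg$colony[["lon"]],
              runif(1, 185, 355), runif(1, 25, 70))
            agenda <- list(depart_at = depart,
              phases = c("commute_out", "forage", "return"))
          }
        }

        if (mode == "colony" && length(agenda$phases) > 0 &&
            tn >= agenda$depart_at) {
          mode <- enter_phase(agenda$phases[1])
        }

        sit <- FALSE; following <- FALSE
        if (mode == "colony") {
          pos <- c(cfg$colony[["lat"]], cfg$colony[["lon"]])
        } else if (mode == "commute_out") {
          pos <- fly_toward(pos, patch, cfg$flight_speed_ms)
          if (haversine_km(pos[1], pos[2], patch[1], patch[2]) < 0.5) {
            mode <- advance()
          }
        } else if (mode == "forage") {
          sit <- runif(1) < (if (was_sitting) 0.95 else 0.2)
          if (!sit) {
            pos <- dest_point_km(pos[1], pos[2], runif(1, 0, 360),
              runif(1, 0.2, 1.5))
            pos <- c(pos[1], pos[2])
          }
          remaining <- remaining - 1
          if (remaining <= 0) mode <- advance()
        } else if (mode == "goto_vessel") {
          vp <- vessel_pos(target, tn)
          pos <- fly_toward(pos, vp, cfg$flight_speed_ms)
          if (haversine_km(pos[1], pos[2], vp[1], vp[2]) <= cfg$mill_km[2]) {
            mode <- advance()
          }
        } else if (mode == "mill") {
          vp <- vessel_pos(target, tn)
          sit <- runif(1) < (if (was_sitting) 0.8 else
            cfg$sit_prob_outside / 4)
          if (!sit) {
            mill_d <- reflect_into(mill_d + rnorm(1, 0, 1),
              cfg$mill_km[1], cfg$mill_km[2])
            cur_b <- bearing_deg(vp[1], vp[2], pos[1], pos[2])
            others <- setdiff(names(vi), target)
            for (try in 1:8) {
              p <- dest_point_km(vp[1], vp[2], cur_b + rnorm(1, 0, 25),
                mill_d)
              if (length(others) == 0) break
              d_oth <- vapply(others, function(v) {
                q <- vessel_pos(v, tn)
                haversine_km(p[1], p[2], q[1], q[2])
              }, 0)
              if (min(d_oth) >= 8) break
            }
            pos <- c(p[1], p[2])
          }
          remaining <- remaining - 1
          if (remaining <= 0) {
            mode <- advance()
          }
        } else if (mode == "approach") {
          vp <- vessel_pos(target, tn)
          vq <- vessel_pos(target, tn - step)
          vsp <- haversine_km(vp[1], vp[2], vq[1], vq[2]) /
            (step / 3600) / 1.852
          if (vsp > 3.2) {
            # hold at a milling distance until the vessel tows slowly
            d_now <- haversine_km(pos[1], pos[2], vp[1], vp[2])
            if (d_now < cfg$mill_km[1]) {
              p <- dest_point_km(vp[1], vp[2],
                bearing_deg(vp[1], vp[2], pos[1], pos[2]), mill_d)
              pos <- c(p[1], p[2])
            }
            lat[i] <- pos[1]; lon[i] <- pos[2]; beh[i] <- "FLIGHT"
            next
          }
          pos <- fly_toward(pos, vp, cfg$flight_speed_ms)
          if (haversine_km(pos[1], pos[2], vp[1], vp[2]) <= follow_d) {
            mode <- advance()
          }
        } else if (mode == "follow") {
          vp <- vessel_pos(target, tn)
          vq <- vessel_pos(target, tn - step)
          vspeed_kn <- haversine_km(vp[1], vp[2], vq[1], vq[2]) /
            (step / 3600) / 1.852
          # abandon a vessel moving faster than a sitting bird can track
          if (vspeed_kn > 3.2) remaining <- 0
          # keep station behind the vessel (net speed = vessel speed),
          # alternating sitting bursts and catch-up flight within the fix
          # interval, so the 5-min behaviour is FOLLOW, not pure SIT
          follow_d <- reflect_into(follow_d + rnorm(1, 0, 0.1),
            0.05, 0.99 * dstar)
          cur_b <- bearing_deg(vp[1], vp[2], pos[1], pos[2])
          p <- dest_point_km(vp[1], vp[2], cur_b + rnorm(1, 0, 6), follow_d)
          pos <- c(p[1], p[2])
          following <- TRUE
          bout_min <- min(bout_min,
            haversine_km(pos[1], pos[2], vp[1], vp[2]))
          remaining <- remaining - 1
          if (remaining <= 0) {
            bouts[[length(bouts) + 1]] <- tibble::tibble(
              vessel_id = target,
              t_start = bout_start, t_end = tn,
              min_distance_km = bout_min)
            mode <- advance()
          }
        } else if (mode == "return") {
          pos <- fly_toward(pos,
            c(cfg$colony[["lat"]], cfg$colony[["lon"]]), cfg$flight_speed_ms)
          if (haversine_km(pos[1], pos[2], cfg$colony[["lat"]],
              cfg$colony[["lon"]]) < 0.3) {
            mode <- advance()   # -> colony
          }
        }
        # small drift while sitting
        if (sit) {
          p <- dest_point_km(pos[1], pos[2], runif(1, 0, 360), 0.02)
          pos <- c(p[1], p[2])
        }
        was_sitting <- sit
        lat[i] <- pos[1]; lon[i] <- pos[2]
        beh[i] <- if (mode == "colony") "COLONY" else if (following)
          "FOLLOW" else if (sit) "SIT" else "FLIGHT"
      }
      list(
        track = tibble::tibble(bird_id = sprintf("B%02d", b),
          sex = if (b %% 2 == 1) "M" else "F",
          scavenger = scav,
          t = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
          lat = lat, lon = lon, behaviour = beh),
        planted = if (length(bouts) == 0) NULL else
          dplyr::mutate(dplyr::bind_rows(bouts),
            bird_id = sprintf("B%02d", b),
            t_start = as.POSIXct(.data$t_start, origin = "1970-01-01",
              tz = "UTC"),
            t_end = as.POSIXct(.data$t_end, origin = "1970-01-01",
              tz = "UTC"), .before = 1))
    })
  })
  planted_events <- purrr::map_dfr(birds, "planted")
  birds <- purrr::map_dfr(birds, "track")

  fixes <- dplyr::select(birds, "bird_id", "t", "lat", "lon")
  plan <- dplyr::select(birds, "bird_id", "t", "sex", "scavenger",
    "behaviour")
  truth_runs <- derive_truth_events(fixes, vessels$truth,
    cfg$attraction_km, cfg$true_interaction_km)
  truth_trips <- derive_truth_trips(birds, cfg)
  list(fixes = fixes, plan = plan, planted_events = planted_events,
    truth_runs = truth_runs, truth_trips = truth_trips, vessels = vessels)
}

reflect_into <- function(x, lo, hi) {
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo), hi)
}

# true interaction episodes from the emitted trajectories: per bird-vessel
# pair, maximal runs of fixes within the attraction distance reaching
# inside the true interaction distance
derive_truth_events <- function(fixes, vessel_truth, attraction_km,
                                true_interaction_km) {
  vi <- vessel_interpolators(vessel_truth)
  purrr::map_dfr(split(fixes, fixes$bird_id), function(g) {
    tn <- as.numeric(g$t)
    purrr::map_dfr(names(vi), function(v) {
      d <- haversine_km(g$lat, g$lon, vi[[v]]$lat(tn), vi[[v]]$lon(tn))
      inr <- d <= attraction_km
      if (!any(inr)) return(NULL)
      r <- rle(inr)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      purrr::map_dfr(which(r$values), function(k) {
        ii <- starts[k]:ends[k]
        if (min(d[ii]) > true_interaction_km) return(NULL)
        tibble::tibble(bird_id = g$bird_id[1], vessel_id = v,
          t_start = g$t[ii[1]], t_end = g$t[ii[length(ii)]],
          min_distance_km = min(d[ii]))
      })
    })
  })
}

derive_truth_trips <- function(birds, cfg) {
  birds |>
    dplyr::mutate(at_sea = .data$behaviour != "COLONY",
      d_col = haversine_km(.data$lat, .data$lon, cfg$colony[["lat"]],
        cfg$colony[["lon"]])) |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::group_modify(function(g, key) {
      r <- rle(g$at_sea)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      purrr::map_dfr(which(r$values), function(k) {
        ii <- starts[k]:ends[k]
        d <- g$d_col[ii]
        seg_len <- sum(haversine_km(
          head(g$lat[ii], -1), head(g$lon[ii], -1),
          tail(g$lat[ii], -1), tail(g$lon[ii], -1)))
        tibble::tibble(start = g$t[ii[1]], end = g$t[ii[length(ii)]],
          max_colony_distance_km = max(d), path_length_km = seg_len)
      })
    }) |>
    dplyr::ungroup()
}

#' Synthesize 25 Hz tri-axial acceleration for a behaviour plan
#'
#' Expands a per-fix behaviour plan (SIT / FLIGHT / COLONY) into
#' per-second ground-truth labels and a matching accelerometer stream:
#' flight alternates flapping bursts (a `wingbeat_hz` sinusoid of ~1 g
#' dynamic amplitude on Z) with short glides (near-static), each maximal
#' flight run starting and ending with flapping; sitting carries
#' wave-induced noise placing mean VeDBA inside the 0.1-1 g band; colony
#' time is near-static and labels as OTHER.
#'
#' @param plan Tibble with `bird_id`, `t` (5-min behaviour plan) as
#'   produced by [simulate_bird_tracks()]; synthesize only the subset you
#'   need, the stream is 25 Hz.
#' @param cfg A [sim_config()].
#' @param rate_hz Sampling rate.
#' @param flap_s,glide_s Burst and glide durations (seconds) inside
#'   flight.
#' @return List with `acc` (tibble `bird_id`, `t`, `ax`, `ay`, `az`) and
#'   `labels` (tibble `bird_id`, `sec`, `label` with SIT / FLAP / GLIDE /
#'   OTHER ground truth).
#' @export
synthesize_accel <- function(plan, cfg, rate_hz = 25, flap_s = 20,
                             glide_s = 10) {
  step <- cfg$gps_step_min * 60
  out <- purrr::map(split(plan, plan$bird_id), function(g) {
    withr::with_seed(cfg$seed + 307L * match(g$bird_id[1],
        sort(unique(plan$bird_id))), {
      g <- dplyr::arrange(g, .data$t)
      sec_label <- rep(dplyr::case_match(g$behaviour,
        "SIT" ~ "SIT", "FLIGHT" ~ "FLIGHT", "FOLLOW" ~ "FOLLOW",
        .default = "OTHER"), each = step)
      r <- rle(sec_label)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        len <- r$lengths[k]
        if (r$values[k] == "FLIGHT") {
          # flap/glide alternation, flap at both run ends
          cyc <- rep(rep(c("FLAP", "GLIDE"), times = c(flap_s, glide_s)),
            length.out = len)
          if (len > flap_s) cyc[(len - flap_s + 1):len] <- "FLAP"
          sec_label[starts[k]:ends[k]] <- cyc
        } else if (r$values[k] == "FOLLOW") {
          # sitting bursts with short catch-up flights behind the vessel
          sit_s <- round(60 * cfg$sit_prob_inside)
          cyc <- rep(rep(c("SIT", "FLAP"), times = c(sit_s, 60 - sit_s)),
            length.out = len)
          sec_label[starts[k]:ends[k]] <- cyc
        }
      }
      n_sec <- length(sec_label)
      n <- n_sec * rate_hz
      tt <- as.numeric(g$t[1]) + (seq_len(n) - 1) / rate_hz
      lab_per_sample <- rep(sec_label, each = rate_hz)

      ax <- rnorm(n, 0, cfg$accel_noise_sd)
      ay <- rnorm(n, 0, cfg$accel_noise_sd)
      az <- 1 + rnorm(n, 0, cfg$accel_noise_sd)
      is_sit <- lab_per_sample == "SIT"
      ax[is_sit] <- rnorm(sum(is_sit), 0, cfg$sit_noise_sd)
      ay[is_sit] <- rnorm(sum(is_sit), 0, cfg$sit_noise_sd)
      az[is_sit] <- 1 + rnorm(sum(is_sit), 0, cfg$sit_noise_sd)
      is_flap <- lab_per_sample == "FLAP"
      az[is_flap] <- az[is_flap] +
        sin(2 * pi * cfg$wingbeat_hz * tt[is_flap])

      list(
        acc = tibble::tibble(bird_id = g$bird_id[1],
          t = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
          ax = ax, ay = ay, az = az),
        labels = tibble::tibble(bird_id = g$bird_id[1],
          sec = as.POSIXct(as.numeric(g$t[1]) + seq_len(n_sec) - 1,
            origin = "1970-01-01", tz = "UTC"),
          label = sec_label))
    })
  })
  list(acc = purrr::map_dfr(out, "acc"),
    labels = purrr::map_dfr(out, "labels"))
}

#' Per-fix sitting fractions from the ground-truth behaviour plan
#'
#' The plan assigns one behaviour to each 5-min fix interval, so the true
#' sitting fraction of the interval is 1 for SIT and 0 otherwise. This is
#' the generator-side equivalent of [add_sit_fraction()] on classified
#' accelerometer seconds, and lets geometry-only studies skip the 25 Hz
#' synthesis.
#'
#' @param fixes Bird fixes.
#' @param plan Behaviour plan from [simulate_bird_tracks()].
#' @param sit_prob_inside Sitting-seconds fraction of FOLLOW intervals
#'   (vessel-following mixes sitting bursts with catch-up flight).
#' @return `fixes` with `sit_fraction`.
#' @export
truth_sit_fraction <- function(fixes, plan, sit_prob_inside = 0.8) {
  dplyr::left_join(fixes,
    dplyr::transmute(plan, bird_id = .data$bird_id, t = .data$t,
      sit_fraction = dplyr::case_match(.data$behaviour,
        "SIT" ~ 1, "FOLLOW" ~ sit_prob_inside, .default = 0)),
    by = c("bird_id", "t"))
}

#' Simulate a complete joint dataset
#'
#' @param cfg A [sim_config()].
#' @return List with `fixes`, `plan`, `vessels_native`, `vessels_truth`,
#'   `planted_events`, `truth_runs`, `truth_trips`, and the `cfg` used.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  vessels <- simulate_vessel_tracks(cfg)
  birds <- simulate_bird_tracks(cfg, vessels)
  list(fixes = birds$fixes, plan = birds$plan,
    vessels_native = vessels$native, vessels_truth = vessels$truth,
    planted_events = birds$planted_events, truth_runs = birds$truth_runs,
    truth_trips = birds$truth_trips, cfg = cfg)
}

#' Write a simulated dataset to disk
#'
#' Emits the CSV dialects consumed by the pipeline (bird GPS, native
#' vessel pings), a ground-truth JSON (planted events, trips, behaviour
#' plan) and a manifest recording the configuration and seed. The same
#' configuration and seed reproduce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param accel_hours Hours of 25 Hz accelerometer data to synthesize per
#'   bird from the start of the study (0 = none; full days are heavy).
#' @return Invisibly, the list of written paths.
#' @export
emit_dataset <- function(cfg, dir, accel_hours = 0) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory ", dir))
  }
  ds <- simulate_dataset(cfg)
  paths <- list(
    bird_gps = file.path(dir, "bird_gps.csv"),
    vessel_pings = file.path(dir, "vessel_pings.csv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    manifest = file.path(dir, "manifest.json"))
  write_bird_gps(ds$fixes, paths$bird_gps)
  write_vessel_pings(ds$vessels_native, paths$vessel_pings)
  if (accel_hours > 0) {
    sub <- ds$plan[ds$plan$t < cfg$start + accel_hours * 3600, ]
    acc <- synthesize_accel(sub, cfg)
    for (b in unique(acc$acc$bird_id)) {
      p <- file.path(dir, paste0("accel_", b, ".csv"))
      write_accel(acc$acc[acc$acc$bird_id == b, ], p)
      paths[[paste0("accel_", b)]] <- p
    }
  }
  truth <- list(
    planted_events = dplyr::mutate(ds$planted_events,
      t_start = format_iso8601(.data$t_start),
      t_end = format_iso8601(.data$t_end)),
    truth_runs = dplyr::mutate(ds$truth_runs,
      t_start = format_iso8601(.data$t_start),
      t_end = format_iso8601(.data$t_end)),
    trips = dplyr::mutate(ds$truth_trips,
      start = format_iso8601(.data$start),
      end = format_iso8601(.data$end)),
    plan = dplyr::mutate(ds$plan, t = format_iso8601(.data$t)))
  jsonlite::write_json(truth, paths$ground_truth, dataframe = "columns",
    auto_unbox = TRUE, digits = 8)
  manifest <- cfg
  manifest$start <- format_iso8601(cfg$start)
  manifest$colony <- as.list(cfg$colony)
  jsonlite::write_json(unclass(manifest), paths$manifest,
    auto_unbox = TRUE, digits = 10)
  invisible(paths)
}

#' Simulate bird-vessel pairs with a planted interaction distance
#'
#' A lightweight generator for studying the breakpoint estimator alone:
#' pair distances are uniform on `(0, max_km)` and each pair's sitting
#' indicator is Bernoulli with probability `sit_prob_inside` below the
#' true distance and `sit_prob_outside` above it.
#'
#' @param n Number of pairs.
#' @param true_km Planted interaction distance.
#' @param sit_prob_inside,sit_prob_outside Sitting probabilities.
#' @param max_km Distance range.
#' @param seed Optional seed (global RNG untouched when given).
#' @return Tibble `distance_km`, `sit_fraction` (0/1).
#' @export
simulate_profile_pairs <- function(n = 5000, true_km = 1.28,
                                   sit_prob_inside = 0.8,
                                   sit_prob_outside = 0.2,
                                   max_km = 8, seed = NULL) {
  gen <- function() {
    d <- runif(n, 0, max_km)
    p <- ifelse(d < true_km, sit_prob_inside, sit_prob_outside)
    tibble::tibble(distance_km = d, sit_fraction = as.numeric(rbinom(n, 1, p)))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate trip records for the group-comparison models
#'
#' Generates per-trip records with a random bird intercept and planted
#' fixed effects at field-realistic magnitudes: the interaction contrast
#' raises daily flight time from 5.28 to 6.22 h and the daily VeDBA sum
#' from 38.63 to 44.77 (partly through flight itself: the VeDBA sum has a
#' positive slope on flight time, since flight is the energetically
#' expensive behaviour), trip length and maximum colony distance are
#' log-normal, and a sex-by-interaction effect (default 9 VeDBA units,
#' females higher when interacting) is planted on the VeDBA response
#' only.
#'
#' @param n_birds Number of birds (half M, half F).
#' @param trips_per_bird Trips per bird.
#' @param p_int Probability a trip has at least one interaction.
#' @param delta_int_flight,delta_int_vedba Planted INT contrasts (the
#'   VeDBA contrast is the total effect, part of it mediated by flight).
#' @param vedba_flight_slope VeDBA-sum units per hour of flight.
#' @param delta_sexint_vedba Planted sex-by-INT interaction on VeDBA.
#' @param sd_bird_flight,sd_resid_flight,sd_bird_vedba,sd_resid_vedba
#'   Variance components.
#' @param seed Optional seed.
#' @return Tibble `bird_id`, `trip_id`, `sex`, `int_flag`,
#'   `daily_vedba_sum`, `daily_flight_time_h`, `trip_length_km`,
#'   `max_colony_distance_km`.
#' @export
simulate_trip_records <- function(n_birds = 32, trips_per_bird = 4,
                                  p_int = 0.5,
                                  delta_int_flight = 0.94,
                                  delta_int_vedba = 6.14,
                                  delta_sexint_vedba = 9,
                                  vedba_flight_slope = 3,
                                  sd_bird_flight = 1.0,
                                  sd_resid_flight = 1.5,
                                  sd_bird_vedba = 3,
                                  sd_resid_vedba = 5,
                                  seed = NULL) {
  gen <- function() {
    birds <- tibble::tibble(
      bird_id = sprintf("B%02d", seq_len(n_birds)),
      sex = rep(c("M", "F"), length.out = n_birds),
      b_flight = rnorm(n_birds, 0, sd_bird_flight),
      b_vedba = rnorm(n_birds, 0, sd_bird_vedba),
      b_len = rnorm(n_birds, 0, 0.15))
    tidyr::expand_grid(birds, trip = seq_len(trips_per_bird)) |>
      dplyr::mutate(
        trip_id = paste0(.data$bird_id, "_T", .data$trip),
        int = rbinom(dplyr::n(), 1, p_int),
        int_flag = ifelse(.data$int == 1, "INT_YES", "INT_NO"),
        female = as.numeric(.data$sex == "F"),
        daily_flight_time_h = pmax(0.2, 5.28 + delta_int_flight * .data$int +
          .data$b_flight + rnorm(dplyr::n(), 0, sd_resid_flight)),
        daily_vedba_sum = pmax(1, 38.63 +
          vedba_flight_slope * (.data$daily_flight_time_h - 5.28) +
          (delta_int_vedba - vedba_flight_slope * delta_int_flight -
            delta_sexint_vedba / 2) * .data$int +
          delta_sexint_vedba * .data$int * .data$female +
          .data$b_vedba + rnorm(dplyr::n(), 0, sd_resid_vedba)),
        trip_length_km = exp(log(243) + log(375 / 243) * .data$int +
          .data$b_len + rnorm(dplyr::n(), 0, 0.45)),
        max_colony_distance_km = pmin(.data$trip_length_km / 2,
          exp(log(53.7) + log(74.5 / 53.7) * .data$int + .data$b_len +
            rnorm(dplyr::n(), 0, 0.5)))) |>
      dplyr::select("bird_id", "trip_id", "sex", "int_flag",
        "daily_vedba_sum", "daily_flight_time_h", "trip_length_km",
        "max_colony_distance_km")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
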