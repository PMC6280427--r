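#' Detect flapping-flight windows from the Z axis
#'
#' Computes the amplitude spectrum of the absolute dorso-ventral (Z)
#' acceleration in consecutive windows, partitions windows into two
#' clusters by k-means on the spectra, and labels as flapping the cluster
#' whose mean peak amplitude inside the wingbeat band is higher. If the
#' two clusters' peak amplitudes differ by less than `tie_tol` (relative),
#' the signal is considered degenerate and no window is flagged.
#'
#' @param acc Tibble with `t` and `az` (g) at a fixed rate for one bird.
#' @param window_s Window length in seconds (default 1).
#' @param band_hz Wingbeat frequency band `(lo, hi)` in Hz.
#' @param rate_hz Sampling rate; inferred when `NULL`.
#' @param tie_tol Relative peak-amplitude difference below which the two
#'   clusters are considered indistinguishable.
#' @param seed Seed for the k-means restarts (the global RNG state is left
#'   untouched).
#' @return Tibble with `win_start` (`POSIXct`) and logical `flap`, one row
#'   per complete window.
#' @export
detect_flapping <- function(acc, window_s = 1, band_hz = c(2, 8),
                            rate_hz = NULL, tie_tol = 0.1, seed = 1) {
  stopifnot(all(c("t", "az") %in% names(acc)))
  if (is.null(rate_hz)) rate_hz <- infer_rate_hz(acc$t)
  k <- round(window_s * rate_hz)
  nwin <- nrow(acc) %/% k
  if (nwin < 10) abort("need at least 10 full windows to cluster spectra")
  z <- abs(acc$az[seq_len(nwin * k)])
  m <- matrix(z, nrow = k)          # one window per column
  m <- sweep(m, 2, colMeans(m))
  amp <- abs(stats::mvfft(m))[2:(k %/% 2 + 1), , drop = FALSE] * 2 / k
  freqs <- seq_len(k %/% 2) / window_s
  feats <- t(amp)

  win_start <- acc$t[seq(1, by = k, length.out = nwin)]
  band_cols <- which(freqs >= band_hz[1] & freqs <= band_hz[2])
  peak <- apply(feats[, band_cols, drop = FALSE], 1, max)

  cl <- tryCatch(
    withr::with_seed(seed, suppressWarnings(
      kmeans(feats, centers = 2, nstart = 10, iter.max = 100)$cluster)),
    error = function(e) NULL)
  flap <- rep(FALSE, nwin)
  if (!is.null(cl)) {
    mp <- tapply(peak, cl, mean)
    if (max(mp) > 0 && (max(mp) - min(mp)) / max(mp) >= tie_tol) {
      flap <- cl == as.integer(names(which.max(mp)))
    }
  }
  tibble::tibble(win_start = win_start, flap = flap)
}

#' Label gliding flight and assemble per-second behaviour labels
#'
#' Shearwater flight alternates flapping bursts with gliding; a non-flapping
#' run is labelled GLIDE when it is bounded on both sides by flapping runs
#' and is no longer than `max_gap_s`. Remaining seconds are SIT when the
#' sitting classifier flagged them, OTHER otherwise.
#'
#' @param per_second Tibble with `sec` (contiguous whole seconds), logical
#'   `flap` and `sit` columns.
#' @param max_gap_s Maximum gap between flapping events still counted as
#'   gliding (seconds).
#' @return The input with a `label` column in
#'   `c("SIT", "FLAP", "GLIDE", "OTHER")`.
#' @export
infer_gliding <- function(per_second, max_gap_s = 30) {
  stopifnot(all(c("sec", "flap", "sit") %in% names(per_second)))
  per_second <- dplyr::arrange(per_second, .data$sec)
  f <- per_second$flap
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  label <- ifelse(f, "FLAP", ifelse(per_second$sit, "SIT", "OTHER"))
  nrun <- length(r$values)
  for (i in seq_len(nrun)) {
    if (!r$values[i] && i > 1 && i < nrun && r$lengths[i] <= max_gap_s) {
      label[starts[i]:ends[i]] <- "GLIDE"
    }
  }
  dplyr::mutate(per_second, label = label)
}

#' Collapse per-second labels into ethogram segments
#'
#' @param seconds Tibble with `bird_id` (optional), `sec`, `label`.
#' @return Tibble `bird_id`, `start`, `end`, `label`; segments partition the
#'   labelled time span (end = start of the next segment).
#' @export
ethogram_segments <- function(seconds) {
  keys <- intersect("bird_id", names(seconds))
  seconds |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$sec)
      r <- rle(g$label)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      tibble::tibble(start = g$sec[starts],
        end = g$sec[ends] + 1, label = r$values)
    }) |>
    dplyr::ungroup()
}

#' Full accelerometer ethogram for one bird
#'
#' Runs the whole behavioural chain: VeDBA with static-component removal,
#' per-second means, GPS-derived ground speed, sitting classification,
#' spectral flapping detection and gliding inference.
#'
#' @param acc Tibble with `t`, `ax`, `ay`, `az` for one bird.
#' @param fixes GPS fixes (`t`, `lat`, `lon`) for the same bird, used for
#'   ground speed.
#' @param bird_id Identifier; taken from `acc$bird_id` when present.
#' @param static_window_s,vedba_lo,vedba_hi,speed_max,window_s,band_hz,max_gap_s,seed
#'   Passed to the component steps (see [compute_vedba()],
#'   [classify_sitting()], [detect_flapping()], [infer_gliding()]).
#' @return An object of class `vb_ethogram`: a list with `seconds`
#'   (per-second labels, VeDBA means and speeds) and `segments`.
#' @export
ethogram <- function(acc, fixes, bird_id = NULL, static_window_s = 1,
                     vedba_lo = 0.1, vedba_hi = 1.0, speed_max = 2.0,
                     window_s = 1, band_hz = c(2, 8), max_gap_s = 30,
                     seed = 1) {
  bird_id <- bird_id %||% (if ("bird_id" %in% names(acc)) acc$bird_id[1] else "bird")
  v <- compute_vedba(acc, static_window_s = static_window_s)
  vs <- vedba_per_second(dplyr::mutate(v, bird_id = bird_id))
  vs$speed_ms <- gps_speed_per_second(fixes, vs$sec)
  vs <- classify_sitting(vs, vedba_lo, vedba_hi, speed_max)

  fl <- detect_flapping(acc, window_s = window_s, band_hz = band_hz,
    seed = seed)
  win_idx <- floor(as.numeric(vs$sec - fl$win_start[1], units = "secs") /
    window_s) + 1
  vs$flap <- fl$flap[pmin(pmax(win_idx, 1L), nrow(fl))]
  vs$flap[is.na(vs$flap)] <- FALSE
  vs <- infer_gliding(vs, max_gap_s = max_gap_s)

  out <- list(seconds = vs, segments = ethogram_segments(vs))
  class(out) <- "vb_ethogram"
  out
}

#' @export
print.vb_ethogram <- function(x, ...) {
  cat("<vb_ethogram> ", nrow(x$seconds), " labelled seconds, ",
    nrow(x$segments), " segments\n", sep = "")
  print(table(x$seconds$label))
  invisible(x)
}

#' Daily flight time and daily sum of VeDBA
#'
#' Days are local (UTC+2) calendar days. Daily flight time is the summed
#' duration of FLAP and GLIDE behaviour in hours; the daily sum of VeDBA
#' adds up the mean VeDBA of every 5-min interval of the day, so its
#' magnitude depends on the number of recorded intervals and is comparable
#' only within a study.
#'
#' @param eth A `vb_ethogram` or a per-second label tibble
#'   (`bird_id`, `sec`, `label`, and `vedba_mean` unless `vedba_seconds`
#'   is given).
#' @param vedba_seconds Optional per-second VeDBA tibble (`sec`,
#'   `vedba_mean`) when `eth` does not carry it.
#' @param interval_s Width of the VeDBA summation interval (default 300 s,
#'   the GPS fix interval).
#' @return Tibble `bird_id`, `date`, `daily_flight_time_h`,
#'   `daily_vedba_sum`. Days with no recorded seconds are omitted.
#' @export
daily_summaries <- function(eth, vedba_seconds = NULL, interval_s = 300) {
  secs <- if (inherits(eth, "vb_ethogram")) eth$seconds else eth
  stopifnot(all(c("sec", "label") %in% names(secs)))
  if (!"bird_id" %in% names(secs)) secs$bird_id <- "bird"
  if (!"vedba_mean" %in% names(secs)) {
    if (is.null(vedba_seconds)) abort("per-second VeDBA means are required")
    secs <- dplyr::left_join(secs, vedba_seconds, by = "sec")
  }
  loc <- to_local_time(secs$sec)
  secs$date <- as.Date(loc, tz = VB_LOCAL_TZ)
  secs$interval <- floor_posix(secs$sec + 2 * 3600, step = interval_s)

  flight <- secs |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(
      daily_flight_time_h = sum(.data$label %in% c("FLAP", "GLIDE")) / 3600,
      .groups = "drop")
  vedba <- secs |>
    dplyr::group_by(.data$bird_id, .data$date, .data$interval) |>
    dplyr::summarise(v = mean(.data$vedba_mean), .groups = "drop") |>
    dplyr::group_by(.data$bird_id, .data$date) |>
    dplyr::summarise(daily_vedba_sum = sum(.data$v), .groups = "drop")
  dplyr::left_join(flight, vedba, by = c("bird_id", "date"))
}
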