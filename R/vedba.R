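#' Vectorial Dynamic Body Acceleration (VeDBA)
#'
#' Separates each acceleration axis into a static (gravitational) and a
#' dynamic component with a centred running mean, and returns the Euclidean
#' norm of the three dynamic components per sample:
#' \deqn{VeDBA = \sqrt{a_x^2 + a_y^2 + a_z^2}}
#' where \eqn{a_x, a_y, a_z} are the dynamic components in g. VeDBA is a
#' standard proxy for energy expenditure in biologging.
#'
#' @param acc Tibble with columns `t` (`POSIXct`), `ax`, `ay`, `az` in g
#'   (X head-tail, Y right-left, Z dorso-ventral) at a fixed sampling rate.
#' @param static_window_s Width (seconds) of the running mean used to
#'   estimate the static component; 1 s is the conventional choice.
#' @param rate_hz Sampling rate; inferred from timestamps when `NULL`.
#' @param static_removal `"running_mean"` (default) or `"none"` for streams
#'   whose gravitational component has already been removed.
#' @param smooth_vedba Optionally apply the same running mean to the VeDBA
#'   series itself (an alternative reading of "1 s smoothing"); off by
#'   default.
#' @return The input tibble with a `vedba` column (g per sample).
#' @export
compute_vedba <- function(acc, static_window_s = 1, rate_hz = NULL,
                          static_removal = c("running_mean", "none"),
                          smooth_vedba = FALSE) {
  static_removal <- match.arg(static_removal)
  stopifnot(all(c("t", "ax", "ay", "az") %in% names(acc)))
  n <- nrow(acc)
  if (n == 0) abort("empty acceleration series")
  if (is.null(rate_hz)) rate_hz <- infer_rate_hz(acc$t)
  k <- max(2L, round(static_window_s * rate_hz))
  if (k %% 2 == 0) k <- k + 1L
  if (static_removal == "running_mean") {
    if (n < k) abort("series shorter than the static window")
    dx <- acc$ax - running_mean(acc$ax, k)
    dy <- acc$ay - running_mean(acc$ay, k)
    dz <- acc$az - running_mean(acc$az, k)
  } else {
    dx <- acc$ax; dy <- acc$ay; dz <- acc$az
  }
  v <- sqrt(dx^2 + dy^2 + dz^2)
  if (smooth_vedba) v <- running_mean(v, k)
  dplyr::mutate(acc, vedba = v)
}

infer_rate_hz <- function(t) {
  if (length(t) < 2) abort("cannot infer sampling rate from a single sample")
  dt <- median(diff(as.numeric(t)))
  if (!is.finite(dt) || dt <= 0) abort("timestamps must be strictly increasing")
  round(1 / dt)
}

# centred running mean with shrinking (partial) windows at the edges
running_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Aggregate a VeDBA series to per-second means
#'
#' @param v Output of [compute_vedba()].
#' @return Tibble with `bird_id` (if present), `sec` (`POSIXct`, whole
#'   seconds) and `vedba_mean`.
#' @export
vedba_per_second <- function(v) {
  stopifnot("vedba" %in% names(v))
  keys <- intersect("bird_id", names(v))
  v |>
    dplyr::mutate(sec = floor_posix(.data$t)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "sec")))) |>
    dplyr::summarise(vedba_mean = mean(.data$vedba), .groups = "drop")
}

floor_posix <- function(t, step = 1) {
  as.POSIXct(floor(as.numeric(t) / step) * step,
    origin = "1970-01-01", tz = "UTC")
}

#' Per-second ground speed from GPS fixes
#'
#' Segment speeds between consecutive fixes (great-circle distance over
#' elapsed time) are linearly interpolated at segment midpoints to the
#' requested seconds; this turns the nominal 5-min GPS speeds into a
#' per-second series for the sitting classifier.
#'
#' @param fixes Tibble with `t`, `lat`, `lon` for one bird.
#' @param seconds `POSIXct` vector of seconds at which speed is wanted.
#' @return Numeric vector of speeds in m/s aligned with `seconds`.
#' @export
gps_speed_per_second <- function(fixes, seconds) {
  if (nrow(fixes) < 2) abort("need at least two fixes to derive speed")
  fixes <- dplyr::arrange(fixes, .data$t)
  tn <- as.numeric(fixes$t)
  dt <- diff(tn)
  if (any(dt <= 0)) abort("fix timestamps must be strictly increasing")
  d_km <- haversine_km(head(fixes$lat, -1), head(fixes$lon, -1),
    tail(fixes$lat, -1), tail(fixes$lon, -1))
  seg_speed <- d_km * 1000 / dt
  if (length(seg_speed) == 1) {
    return(rep(seg_speed, length(seconds)))
  }
  mid <- head(tn, -1) + dt / 2
  approx(mid, seg_speed, xout = as.numeric(seconds), rule = 2)$y
}

#' Classify sitting-on-the-water seconds
#'
#' A second is flagged SIT when its mean VeDBA lies inside the
#' `[vedba_lo, vedba_hi]` band (wave-induced motion of a floating bird)
#' and the GPS-derived ground speed does not exceed `speed_max` (the bird
#' is not in flight).
#'
#' @param per_second Tibble with columns `vedba_mean` (g) and `speed_ms`
#'   (m/s), one row per second.
#' @param vedba_lo,vedba_hi VeDBA band in g; defaults 0.1 and 1.0.
#' @param speed_max Maximum ground speed in m/s; default 2.0.
#' @return The input with a logical `sit` column.
#' @export
classify_sitting <- function(per_second, vedba_lo = 0.1, vedba_hi = 1.0,
                             speed_max = 2.0) {
  if (!all(c("vedba_mean", "speed_ms") %in% names(per_second))) {
    abort("per_second needs aligned `vedba_mean` and `speed_ms` columns")
  }
  if (anyNA(per_second$vedba_mean) || anyNA(per_second$speed_ms)) {
    abort("vedba_mean and speed_ms must be complete (misaligned inputs?)")
  }
  dplyr::mutate(per_second,
    sit = .data$vedba_mean >= vedba_lo & .data$vedba_mean <= vedba_hi &
      .data$speed_ms <= speed_max)
}
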