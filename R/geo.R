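#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length, so the function works both for pairs of
#' points and for whole tracks.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  if (n == 0) return(numeric(0))
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

check_coords <- function(lat, lon) {
  ok <- is.finite(lat) & is.finite(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  if (!all(ok)) {
    abort("invalid coordinates: lat must be in [-90, 90], lon in [-180, 180]")
  }
  invisible(TRUE)
}

#' Convert timestamps between UTC and the study's local time (UTC+2)
#'
#' Diel summaries use a fixed UTC+2 offset with no daylight-saving logic;
#' all internal processing stays in UTC.
#'
#' @param t A `POSIXct` vector.
#' @return The same instants, represented in the other timezone.
#' @examples
#' to_local_time(as.POSIXct("2023-07-01 04:00", tz = "UTC"))
#' @export
to_local_time <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  lubridate::with_tz(t, VB_LOCAL_TZ)
}

#' @rdname to_local_time
#' @export
to_utc_time <- function(t) {
  stopifnot(inherits(t, "POSIXct"))
  lubridate::with_tz(t, "UTC")
}

# Solar position following the NOAA Solar Calculator equations.
# Returns apparent solar elevation in degrees for UTC times.
solar_elevation_deg <- function(t, lat, lon) {
  stopifnot(inherits(t, "POSIXct"))
  t <- lubridate::with_tz(t, "UTC")
  jd <- as.numeric(t) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  deg2rad <- pi / 180

  gmls <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(gmas * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg2rad) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(oc * deg2rad) * sin(sal * deg2rad)) / deg2rad

  vary <- tan(oc / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (vary * sin(2 * gmls * deg2rad) -
    2 * eeo * sin(gmas * deg2rad) +
    4 * eeo * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
    0.5 * vary^2 * sin(4 * gmls * deg2rad) -
    1.25 * eeo^2 * sin(2 * gmas * deg2rad))

  mins_utc <- (as.numeric(t) %% 86400) / 60
  tst <- (mins_utc + eqtime + 4 * lon) %% 1440
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)
  cosz <- sin(lat * deg2rad) * sin(decl * deg2rad) +
    cos(lat * deg2rad) * cos(decl * deg2rad) * cos(ha * deg2rad)
  cosz <- pmin(1, pmax(-1, cosz))
  90 - acos(cosz) / deg2rad
}

#' Night mask from solar elevation
#'
#' Flags timestamps that fall between local sunset and sunrise at a site,
#' using a standard solar-position algorithm. The horizon threshold is the
#' conventional -0.833 degrees (refraction plus solar radius) and is
#' configurable.
#'
#' @param t `POSIXct` timestamps (any timezone; instants are what matter).
#' @param lat,lon Site coordinates in decimal degrees.
#' @param horizon_deg Solar elevation (degrees) below which it is night.
#' @return Logical vector, `TRUE` at night.
#' @export
night_mask <- function(t, lat, lon, horizon_deg = -0.833) {
  check_coords(lat, lon)
  if (abs(lat) > 66) {
    abort("night_mask does not handle polar day/night latitudes (|lat| > 66)")
  }
  solar_elevation_deg(t, lat, lon) < horizon_deg
}

#' Sunrise and sunset times for a date and site
#'
#' @param date A `Date` (or coercible) vector.
#' @param lat,lon Site coordinates in decimal degrees.
#' @param horizon_deg Solar elevation defining the horizon crossing.
#' @return A tibble with `date`, `sunrise`, `sunset` (`POSIXct`, UTC).
#' @export
sun_times <- function(date, lat, lon, horizon_deg = -0.833) {
  check_coords(lat, lon)
  date <- as.Date(date)
  # locate the crossings on a 1-min grid, then refine linearly
  purrr::map_dfr(date, function(d) {
    t0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    tt <- t0 + seq(0, 86340, by = 60)
    el <- solar_elevation_deg(tt, lat, lon)
    up <- el >= horizon_deg
    rise_i <- which(!up[-length(up)] & up[-1])
    set_i <- which(up[-length(up)] & !up[-1])
    cross <- function(i) {
      if (length(i) == 0) return(as.POSIXct(NA, tz = "UTC"))
      i <- i[1]
      frac <- (horizon_deg - el[i]) / (el[i + 1] - el[i])
      tt[i] + 60 * frac
    }
    tibble::tibble(date = d, sunrise = cross(rise_i), sunset = cross(set_i))
  })
}

# spherical destination point, R = 6371 km (consistent with haversine_km)
dest_point_km <- function(lat, lon, bearing_deg, d_km) {
  dr <- pi / 180
  la <- lat * dr; lo <- lon * dr; th <- bearing_deg * dr
  delta <- d_km / 6371
  la2 <- asin(sin(la) * cos(delta) + cos(la) * sin(delta) * cos(th))
  lo2 <- lo + atan2(sin(th) * sin(delta) * cos(la),
    cos(delta) - sin(la) * sin(la2))
  cbind(lat = la2 / dr, lon = ((lo2 / dr + 540) %% 360) - 180)
}

# initial great-circle bearing in degrees [0, 360)
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  dr <- pi / 180
  dl <- (lon2 - lon1) * dr
  y <- sin(dl) * cos(lat2 * dr)
  x <- cos(lat1 * dr) * sin(lat2 * dr) -
    sin(lat1 * dr) * cos(lat2 * dr) * cos(dl)
  (atan2(y, x) / dr) %% 360
}
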