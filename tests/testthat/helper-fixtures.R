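# shared toy builders; all fixtures are generated in code

t_utc <- function(x) as.POSIXct(x, tz = "UTC")

toy_colony <- c(lat = 35.8592, lon = 12.8594)

# fixes along a bearing from the colony, one per gps step
toy_track <- function(dists_km, bearing = 90, start = t_utc("2023-06-15 06:00:00"),
                      step_s = 300, bird_id = "B1") {
  pts <- vesselbird:::dest_point_km(toy_colony[["lat"]], toy_colony[["lon"]],
    bearing, dists_km)
  tibble::tibble(bird_id = bird_id,
    t = start + (seq_along(dists_km) - 1) * step_s,
    lat = pts[, 1], lon = pts[, 2])
}

# accel stream at 25 Hz from a per-second spec
toy_accel <- function(seconds, az_fun, rate = 25,
                      start = t_utc("2023-06-15 06:00:00")) {
  tt <- seq(0, seconds - 1 / rate, by = 1 / rate)
  tibble::tibble(t = start + tt, ax = 0, ay = 0, az = az_fun(tt))
}

# gridded vessel track (already on the 10-min grid) at fixed positions
toy_vessel_grid <- function(dists_km, bearing = 90, vessel_id = "V1",
                            start = t_utc("2023-06-15 06:00:00"),
                            gear = "trawl") {
  pts <- vesselbird:::dest_point_km(toy_colony[["lat"]], toy_colony[["lon"]],
    bearing, dists_km)
  tibble::tibble(vessel_id = vessel_id,
    t = start + (seq_along(dists_km) - 1) * 600,
    lat = pts[, 1], lon = pts[, 2], speed_kn = 3, heading_deg = 90,
    gear = gear, activity = "fishing")
}
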