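# City-centre anchor coordinates for the tracking scenarios (approximate
# WGS84 locations; only relative geometry matters).
CITY_COORDS <- list(
  kaohsiung = c(22.6273, 120.3014),
  taipei    = c(25.0330, 121.5654),
  new_taipei = c(25.0120, 121.4657),
  taoyuan   = c(24.9937, 121.3010)
)

home_stay_check <- function(seed, home) {
  force(seed); force(home)
  function() {
    track <- simulate_track("stay_home", home = home, duration = 1200,
                            seed = seed)
    fence <- geofence("home", center = home, radius_m = 50, is_home = TRUE)
    ev <- detect_fence_events(track, list(fence))
    lo <- detect_loitering(track, radius_m = 45, dwell_s = 300)
    smry <- track_summary(track)
    all(in_fence(fence, track$lat, track$lon)) &&       # never leaves home
      !any(ev$kind %in% c("EXIT", "AWAY")) &&           # so no away events
      nrow(lo) >= 1L &&                                 # dwell is detected
      (lo$t_end[1L] - lo$t_start[1L]) >= 300 &&
      smry$duration_s == 1200
  }
}

facility_check <- function(seed, center) {
  force(seed); force(center)
  function() {
    track <- simulate_track("wander", home = center, duration = 900,
                            speed = 0.3, seed = seed)
    half <- 200 / (pi * EARTH_RADIUS_M / 180)           # ~200 m in degrees
    ring <- data.frame(
      lat = center[1L] + c(-half, -half, half, half),
      lon = center[2L] + c(-half, half, half, -half))
    fence <- geofence("facility", ring = ring)
    ev <- detect_fence_events(track, list(fence))
    all(in_fence(fence, track$lat, track$lon)) &&       # stays on the grounds
      nrow(ev) == 0L
  }
}

city_track_check <- function(seed, origin, speed = 1.5, duration = 600,
                             with_destination = FALSE) {
  force(seed); force(origin); force(speed); force(duration)
  force(with_destination)
  function() {
    track <- simulate_track("commute", home = origin, duration = duration,
                            speed = speed, seed = seed)
    fences <- list(geofence("origin", center = origin, radius_m = 100,
                            is_home = TRUE))
    if (with_destination) {
      dest <- c(track$lat[nrow(track)], track$lon[nrow(track)])
      fences <- c(fences, list(geofence("destination", center = dest,
                                        radius_m = 150)))
    }
    ev <- detect_fence_events(track, fences)
    expected_m <- speed * duration
    smry <- track_summary(track)
    ok <- sum(ev$kind == "EXIT" & ev$fence_id == "origin") == 1L &&
      sum(ev$kind == "AWAY") == 1L &&
      abs(smry$distance_m - expected_m) / expected_m < 0.05
    if (with_destination)
      ok <- ok && sum(ev$kind == "ENTER" & ev$fence_id == "destination") == 1L
    ok
  }
}

#' The ten location-tracking stability scenarios
#'
#' Synthetic analogues of a ten-wearer daily tracking campaign: two daily
#' home stays (the wearer jitters within the home fence all day; expected:
#' no exit or away events, a loitering interval, full-duration summary),
#' three nursing-facility stays (a slow wander that never leaves the
#' facility polygon fence), and five city-tracking trips (a commute that
#' exits the home fence exactly once, raising an AWAY event, with the
#' summary distance matching speed times duration within 5%; the two
#' inter-city trips additionally enter a destination fence). Each scenario
#' carries a deterministic derived seed, so the protocol is reproducible.
#'
#' @param seed master seed for the scenario tracks.
#' @return list of scenario objects for [run_location_protocol()], each
#'   `list(name, check)`.
#' @export
location_scenarios <- function(seed = 2026L) {
  s <- function(k) (seed + 17L * k) %% .Machine$integer.max
  home1 <- c(24.95, 121.22)
  home2 <- c(25.04, 121.55)
  list(
    list(name = "daily_home_stay_wearer1",
         check = home_stay_check(s(1L), home1)),
    list(name = "daily_home_stay_wearer2",
         check = home_stay_check(s(2L), home2)),
    list(name = "daily_nursing_home_wearer3",
         check = facility_check(s(3L), c(24.96, 121.30))),
    list(name = "daily_nursing_home_wearer4",
         check = facility_check(s(4L), c(24.97, 121.31))),
    list(name = "daily_nursing_home_wearer5",
         check = facility_check(s(5L), c(24.98, 121.32))),
    list(name = "city_tracking_kaohsiung_wearer6",
         check = city_track_check(s(6L), CITY_COORDS$kaohsiung)),
    list(name = "city_tracking_taipei_wearer7",
         check = city_track_check(s(7L), CITY_COORDS$taipei)),
    list(name = "city_tracking_taipei_to_new_taipei_wearer8",
         check = city_track_check(s(8L), CITY_COORDS$taipei, speed = 2,
                                  duration = 900, with_destination = TRUE)),
    list(name = "city_tracking_taoyuan_wearer9",
         check = city_track_check(s(9L), CITY_COORDS$taoyuan)),
    list(name = "city_tracking_taipei_to_taoyuan_wearer10",
         check = city_track_check(s(10L), CITY_COORDS$taipei, speed = 2,
                                  duration = 900, with_destination = TRUE))
  )
}
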