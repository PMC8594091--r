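test_that("haversine distance matches the closed form and is symmetric", {
  expect_equal(haversine_m(10, 20, 10, 20), 0)
  # one degree of latitude on a 6371 km sphere
  expect_equal(haversine_m(0, 0, 1, 0), pi * 6371000 / 180, tolerance = 1 / 111194)
  expect_lt(abs(haversine_m(0, 0, 1, 0) - 111194.9), 1)
  set.seed(2)
  for (i in 1:10) {
    a <- c(runif(1, -80, 80), runif(1, -179, 179))
    b <- c(runif(1, -80, 80), runif(1, -179, 179))
    expect_equal(haversine_m(a[1], a[2], b[1], b[2]),
                 haversine_m(b[1], b[2], a[1], a[2]))
  }
  expect_error(haversine_m(95, 0, 0, 0), "WGS84")
})

test_that("fence transitions produce ordered enter/exit and home/away events", {
  center <- c(24.95, 121.22)
  # straight west-to-east pass through the fence centre
  lon <- center[2] + seq(-0.01, 0.01, length.out = 201)
  track <- geo_track(data.frame(t = 0:200, lat = center[1], lon = lon))
  fence <- geofence("home", center = center, radius_m = 300, is_home = TRUE)
  ev <- detect_fence_events(track, list(fence))
  expect_identical(ev$kind, c("ENTER", "HOME", "EXIT", "AWAY"))
  expect_true(all(diff(ev$t_start) >= 0))
  # entirely inside: no transition, no event
  inside <- geo_track(data.frame(t = 0:10, lat = center[1],
                                 lon = center[2] + 1e-5 * (0:10)))
  expect_identical(nrow(detect_fence_events(inside, list(fence))), 0L)
  expect_identical(nrow(detect_fence_events(track, list())), 0L)
})

test_that("a point exactly on the circle boundary counts as inside", {
  center <- c(0, 0)
  fence <- geofence("f", center = center, radius_m = pi * 6371000 / 180)
  # (1, 0) lies exactly on the boundary (one degree of latitude)
  expect_true(in_fence(fence, 1, 0))
  expect_false(in_fence(fence, 1.001, 0))
})

test_that("polygon membership uses closed-boundary even-odd ray casting", {
  ring <- data.frame(lat = c(0, 0, 1, 1), lon = c(0, 1, 1, 0))
  f <- geofence("sq", ring = ring)
  expect_true(in_fence(f, 0.5, 0.5))
  expect_false(in_fence(f, 1.5, 0.5))
  expect_true(in_fence(f, 0, 0.5))    # on an edge
  expect_true(in_fence(f, 0, 0))      # on a vertex
})

test_that("enter and exit strictly alternate per fence on any track", {
  center <- c(24.95, 121.22)
  fence <- geofence("f", center = center, radius_m = 150)
  # deterministic zigzag: repeatedly leaves and re-enters the fence
  offsets_m <- c(0, 400, 50, 500, 100, 600, 0, 300, 700)
  lon <- center[2] + offsets_m / (pi * 6371000 / 180 * cos(center[1] * pi / 180))
  zig <- geo_track(data.frame(t = seq_along(lon) - 1, lat = center[1],
                              lon = lon))
  ev <- detect_fence_events(zig, list(fence))
  kinds <- ev$kind[ev$kind %in% c("ENTER", "EXIT")]
  expect_gt(length(kinds), 3L)
  expect_true(all(kinds[-1L] != kinds[-length(kinds)]))
  for (k in 1:5) {
    track <- simulate_track("wander", center, duration = 900, speed = 3,
                            seed = 100L + k)
    evw <- detect_fence_events(track, list(fence))
    kw <- evw$kind[evw$kind %in% c("ENTER", "EXIT")]
    if (length(kw) > 1L)
      expect_true(all(kw[-1L] != kw[-length(kw)]))
  }
})

test_that("loitering is found for dwells and absent for steady walking", {
  home <- c(24.95, 121.22)
  stat <- simulate_track("stay_home", home, duration = 600, seed = 5L)
  lo <- detect_loitering(stat, radius_m = 45, dwell_s = 300)
  expect_identical(nrow(lo), 1L)
  expect_equal(lo$t_start, 0)
  expect_equal(lo$t_end, 600)
  walk <- simulate_track("commute", home, duration = 600, speed = 1, seed = 5L)
  expect_identical(nrow(detect_loitering(walk, radius_m = 20,
                                         dwell_s = 300)), 0L)
  shorttrack <- simulate_track("stay_home", home, duration = 100, seed = 5L)
  expect_identical(nrow(detect_loitering(shorttrack, radius_m = 45,
                                         dwell_s = 300)), 0L)
  expect_error(detect_loitering(stat, radius_m = 0, dwell_s = 10), "positive")
})

test_that("loitering detection is invariant to translating the track", {
  home <- c(24.95, 121.22)
  tr <- simulate_track("wander", home, duration = 900, speed = 0.5, seed = 7L)
  lo1 <- detect_loitering(tr, radius_m = 30, dwell_s = 200)
  shifted <- as.data.frame(tr)
  shifted$lat <- shifted$lat + 0.5
  shifted$lon <- shifted$lon + 0.5
  lo2 <- detect_loitering(geo_track(shifted), radius_m = 30, dwell_s = 200)
  expect_identical(nrow(lo1), nrow(lo2))
  expect_equal(lo1$t_start, lo2$t_start, tolerance = 1)
})

test_that("track summaries report distance, steps and reversal invariance", {
  home <- c(24.95, 121.22)
  single <- geo_track(data.frame(t = 0, lat = home[1], lon = home[2]))
  s0 <- track_summary(single)
  expect_identical(s0$distance_m, 0)
  expect_identical(s0$steps, 0L)
  com <- simulate_track("commute", home, duration = 600, speed = 1, seed = 9L)
  sc <- track_summary(com)
  expect_lt(abs(sc$distance_m - 600) / 600, 0.05)
  rev_df <- as.data.frame(com)
  rev_df <- rev_df[nrow(rev_df):1, ]
  rev_df$t <- sort(rev_df$t)
  expect_equal(track_summary(geo_track(rev_df))$distance_m, sc$distance_m)
  # 20 injected 1.5 g peaks, 0.5 s apart, must count as exactly 20 steps
  fs <- 50
  n <- 600L
  az <- rep(1, n)
  for (k in 1:20) az[10L + 25L * (k - 1L)] <- 1.5
  imu <- imu_series(data.frame(t = (0:(n - 1)) / fs, ax = 0, ay = 0, az = az,
                               gx = 0, gy = 0, gz = 0), fs)
  sw <- track_summary(single, imu = imu)
  expect_identical(sw$steps, 20L)
  expect_equal(sw$calories_kcal, 0.8)
})

test_that("fences and events round-trip through GeoJSON and JSON lines", {
  fences <- list(
    geofence("home", center = c(24.95, 121.22), radius_m = 80,
             is_home = TRUE),
    geofence("park", ring = data.frame(lat = c(24.9, 24.9, 24.91, 24.91),
                                       lon = c(121.2, 121.21, 121.21, 121.2))))
  gj <- tempfile(fileext = ".geojson")
  write_fences_geojson(fences, gj)
  back <- read_fences_geojson(gj)
  expect_length(back, 2L)
  expect_identical(back[[1L]]$kind, "circle")
  expect_true(back[[1L]]$is_home)
  expect_equal(back[[1L]]$radius_m, 80)
  expect_identical(back[[2L]]$kind, "polygon")
  expect_equal(unname(back[[2L]]$ring[1L, ]), c(24.9, 121.2))
  track <- simulate_track("commute", c(24.95, 121.22), duration = 300,
                          speed = 1, seed = 2L)
  ev <- detect_fence_events(track, list(fences[[1L]]))
  jl <- tempfile(fileext = ".jsonl")
  write_events_jsonl(ev, jl)
  lines <- readLines(jl)
  expect_identical(length(lines), nrow(ev))
  expect_identical(jsonlite::fromJSON(lines[1L])$kind, ev$kind[1L])
})

test_that("track CSV round-trips", {
  tr <- simulate_track("wander", c(24.95, 121.22), duration = 60, seed = 3L)
  path <- tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  back <- read_track_csv(path, wearer_id = "w1")
  expect_equal(back$lat, tr$lat, tolerance = 1e-9)
  expect_identical(attr(back, "wearer_id"), "w1")
})
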