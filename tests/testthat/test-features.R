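test_that("signal vector magnitude matches hand values and a brute-force loop", {
  expect_equal(svm_g(0, 0, 1), 1.0)
  expect_equal(svm_g(0.6, 0.8, 0), 1.0)
  expect_equal(svm_g(0, 0, 0), 0.0)
  expect_error(svm_g(NA, 0, 1), "finite")
  tr <- simulate_fall("FALL_FORWARD", simulation_config(seed = 21L))
  expect_equal(svm_g(tr$series), brute_svm(as.data.frame(tr$series)),
               tolerance = 1e-12)
})

test_that("signal magnitude area is the mean summed absolute acceleration", {
  const1 <- data.frame(ax = rep(0, 10), ay = rep(0, 10), az = rep(1, 10))
  expect_equal(sma_g(const1), 1.0)
  const2 <- data.frame(ax = rep(0.6, 8), ay = rep(0.8, 8), az = rep(0, 8))
  expect_equal(sma_g(const2), 1.4)
  alt <- data.frame(ax = rep(c(1, -1), 10), ay = 0, az = 0)
  expect_equal(sma_g(alt), brute_sma(alt))
  expect_equal(sma_g(alt), 1.0)
  tr <- simulate_adl("ADL_WALK", 4, simulation_config(seed = 22L))
  expect_equal(sma_g(as.data.frame(tr$series)),
               brute_sma(as.data.frame(tr$series)), tolerance = 1e-12)
  expect_error(sma_g(const1[0, ]), "empty")
})

test_that("tilt angles handle upright, horizontal and inverted postures", {
  up <- tilt_angles(0, 0, 1)
  expect_equal(unlist(up), c(rho = 0, phi = 0, theta = 0))
  horiz <- tilt_angles(1, 0, 0)
  expect_equal(unlist(horiz), c(rho = 90, phi = 0, theta = 90))
  inv <- tilt_angles(0, 0, -1)
  expect_equal(inv$theta, 180)
  expect_error(tilt_angles(0, 0, 0), "zero-magnitude")
})

test_that("theta recovers the inclination of any rotation of gravity", {
  # oracle: rotate (0,0,1) by an explicit rotation matrix, compare theta
  # with the rotation's inclination angle
  set.seed(31)
  for (i in 1:25) {
    incl <- runif(1, 0, 180)
    azim <- runif(1, 0, 360)
    ri <- incl * pi / 180; ra <- azim * pi / 180
    v <- c(sin(ri) * cos(ra), sin(ri) * sin(ra), cos(ri))
    ta <- tilt_angles(v[1L], v[2L], v[3L])
    expect_equal(ta$theta, incl, tolerance = 1e-9)
  }
})

test_that("noise filtering preserves DC, attenuates spikes, keeps length", {
  fs <- 50
  n <- 100L
  const <- imu_series(data.frame(t = (0:(n - 1)) / fs, ax = 0.2, ay = -0.1,
                                 az = 0.97, gx = 1, gy = -2, gz = 0), fs)
  out <- noise_filter(const)
  expect_equal(out$az, const$az, tolerance = 1e-9)
  expect_equal(nrow(out), n)
  spike <- as.data.frame(const)
  spike$az[50L] <- spike$az[50L] + 10
  sp <- noise_filter(imu_series(spike, fs))
  expect_lt(max(sp$az), 10)
  short <- imu_series(data.frame(t = (0:5) / fs, ax = 0, ay = 0, az = 1,
                                 gx = 0, gy = 0, gz = 0), fs)
  expect_error(noise_filter(short), "9 samples")
  expect_error(noise_filter(const, cutoff = 30), "Nyquist")
})

test_that("gravity separation is exact, static-correct and band-selective", {
  fs <- 50
  t <- (0:499) / fs
  static <- imu_series(data.frame(t = t, ax = 0, ay = 0, az = 1,
                                  gx = 0, gy = 0, gz = 0), fs)
  sep <- separate_gravity(static)
  expect_equal(sep$gravity$az, rep(1, 500), tolerance = 1e-9)
  expect_lt(max(abs(sep$body$az)), 1e-9)
  wob <- as.data.frame(static)
  wob$az <- 1 + 0.5 * sin(2 * pi * 5 * t)
  sepw <- separate_gravity(imu_series(wob, fs))
  expect_equal(sepw$gravity$az + sepw$body$az, wob$az, tolerance = 1e-12)
  # the 5 Hz component must live in the body series, not the gravity one
  amp5 <- function(x) Mod(stats::fft(x - mean(x)))[5 * length(x) / 50 + 1]
  expect_lt(amp5(sepw$gravity$az), 0.05 * amp5(wob$az))
  expect_gt(amp5(sepw$body$az), 0.95 * amp5(wob$az))
  expect_error(separate_gravity(static, cutoff = 25), "Nyquist")
})

test_that("sliding windows have fixed length, stride and trailing drop", {
  fs <- 50
  t <- (0:499) / fs
  s <- imu_series(data.frame(t = t, ax = 0, ay = 0, az = 1,
                             gx = 0, gy = 0, gz = 0), fs)
  ws <- sliding_windows(s, window_config(2.56, 0.5))
  expect_length(ws, 6L)  # floor((500 - 128) / 64) + 1
  expect_true(all(vapply(ws, function(w) nrow(w$data), integer(1L)) == 128L))
  tiled <- sliding_windows(s, window_config(2, 0))
  starts <- vapply(tiled, function(w) w$t_start, numeric(1L))
  expect_equal(diff(starts), rep(2, length(starts) - 1L))
  short <- imu_series(data.frame(t = (0:49) / fs, ax = 0, ay = 0, az = 1,
                                 gx = 0, gy = 0, gz = 0), fs)
  expect_identical(sliding_windows(short, window_config(2.56, 0.5)), list())
  # every non-trailing sample is covered at least once
  covered <- logical(500)
  for (w in ws) {
    i0 <- round(w$t_start * fs) + 1L
    covered[i0:(i0 + 127L)] <- TRUE
  }
  expect_true(all(covered[1:448]))
  expect_error(window_config(overlap = 1), "overlap")
  expect_error(window_config(width = 0), "width")
})

test_that("window CSV serialisation writes one row per window", {
  tr <- simulate_adl("ADL_WALK", 6, simulation_config(seed = 41L))
  ws <- sliding_windows(tr$series, window_config(), label = "ADL_WALK")
  path <- tempfile(fileext = ".csv")
  write_windows_csv(ws, path)
  flat <- read.csv(path)
  expect_identical(nrow(flat), length(ws))
  expect_identical(flat$label[1L], "ADL_WALK")
})
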