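test_that("simulated falls realise the four phases for every fall type", {
  cfg <- simulation_config(seed = 3L)
  for (lab in activity_labels(falls_only = TRUE)) {
    tr <- simulate_fall(lab, cfg)
    s <- tr$series
    ann <- tr$annotation
    expect_s3_class(s, "imu_series")
    expect_true(ann$t_freefall_start < ann$t_impact)
    expect_true(ann$t_impact < ann$t_motionless_start)
    expect_true(ann$t_motionless_start < ann$t_motionless_end)
    v <- brute_svm(as.data.frame(s))
    quiet <- v[s$t < ann$t_freefall_start - 0.2]
    expect_true(all(abs(quiet - 1) < 6 * cfg$noise_sd))
    ff <- v[s$t >= ann$t_freefall_start & s$t < ann$t_impact]
    expect_lte(min(ff), cfg$freefall_floor + 3 * cfg$noise_sd)
    expect_lt(min(ff), 1.0)
    expect_gte(max(v), cfg$impact_peak - 3 * cfg$noise_sd)
    # impact is a genuine peak: the SVM first difference reverses sign
    ipk <- which.max(v)
    expect_gt(v[ipk] - v[ipk - 1L], 0)
    expect_gt(v[ipk] - v[ipk + 1L], 0)
    # final orientation rotated >= 45 degrees from initial
    mot <- s$t >= ann$t_motionless_start
    pre <- s$t < ann$t_freefall_start
    g0 <- c(mean(s$ax[pre]), mean(s$ay[pre]), mean(s$az[pre]))
    g1 <- c(mean(s$ax[mot]), mean(s$ay[mot]), mean(s$az[mot]))
    ang <- acos(sum(g0 * g1) / sqrt(sum(g0^2) * sum(g1^2))) * 180 / pi
    expect_gte(ang, 45)
  }
})

test_that("noiseless fall has exact quiet gravity and exact dip floor", {
  cfg <- simulation_config(noise_sd = 0, gyro_noise_sd = 0, seed = 1L)
  tr <- simulate_fall("FALL_BACK_RIGHT", cfg)
  v <- svm_g(tr$series)
  quiet <- v[tr$series$t < tr$annotation$t_freefall_start]
  expect_equal(quiet, rep(1, length(quiet)), tolerance = 1e-12)
  ff <- v[tr$series$t >= tr$annotation$t_freefall_start &
            tr$series$t < tr$annotation$t_impact]
  expect_equal(min(ff), cfg$freefall_floor, tolerance = 1e-9)
  expect_equal(max(v), cfg$impact_peak, tolerance = 1e-9)
})

test_that("left and right falls with the same seed mirror in the lateral axis", {
  cfg <- simulation_config(seed = 9L)
  l <- simulate_fall("FALL_LEFT", cfg)
  r <- simulate_fall("FALL_RIGHT", cfg)
  mot_l <- l$series$t >= l$annotation$t_motionless_start
  mot_r <- r$series$t >= r$annotation$t_motionless_start
  # same seed means identical noise draws, so the deterministic parts mirror
  expect_lt(abs(mean(l$series$ay[mot_l]) + mean(r$series$ay[mot_r])), 0.02)
  expect_lt(abs(mean(l$series$ax[mot_l]) - mean(r$series$ax[mot_r])), 0.02)
  expect_lt(abs(mean(l$series$az[mot_l]) - mean(r$series$az[mot_r])), 0.02)
  expect_lt(mean(l$series$ay[mot_l]), -0.5)
  expect_gt(mean(r$series$ay[mot_r]), 0.5)
})

test_that("simulation is bit-reproducible for identical configurations", {
  cfg <- simulation_config(seed = 77L)
  a <- simulate_fall("TRIP_OVER", cfg)
  b <- simulate_fall("TRIP_OVER", cfg)
  expect_identical(a$series, b$series)
  w1 <- simulate_adl("ADL_WALK", 5, cfg)
  w2 <- simulate_adl("ADL_WALK", 5, cfg)
  expect_identical(w1$series, w2$series)
})

test_that("label and configuration validation rejects bad inputs", {
  expect_error(simulate_fall("ADL_WALK"), "fall label")
  expect_error(simulate_adl("FALL_LEFT", 10), "non-fall")
  expect_error(simulation_config(freefall_floor = 1.2), "below 1")
  expect_error(simulation_config(impact_peak = 0.9), "exceed 1")
  expect_error(simulate_adl("ADL_STAND", duration = 0), "positive")
})

test_that("non-fall activities never carry the weight-loss plus impact pair", {
  cfg <- simulation_config(seed = 2L)
  for (lab in c("ADL_WALK", "ADL_SIT_DOWN", "ADL_LIE_DOWN", "ADL_STAND")) {
    tr <- simulate_adl(lab, 10, cfg)
    v <- brute_svm(as.data.frame(tr$series))
    fs <- imu_fs(tr$series)
    k <- round(0.2 * fs)
    horizon <- round(1 * fs)
    signature <- FALSE
    for (i in seq_len(length(v) - k + 1L)) {
      if (mean(v[i:(i + k - 1L)]) <= cfg$freefall_floor) {
        upto <- min(length(v), i + k - 1L + horizon)
        if (max(v[(i + k - 1L):upto]) >= cfg$impact_peak) signature <- TRUE
      }
    }
    expect_false(signature, label = paste("fall signature absent in", lab))
  }
})

test_that("sit-down dips stay above the free-fall floor (confusable ADL)", {
  tr <- simulate_adl("ADL_SIT_DOWN", 10, simulation_config(seed = 2L))
  expect_gt(min(brute_svm(as.data.frame(tr$series))),
            simulation_config()$freefall_floor)
})

test_that("noiseless standing is constant upright gravity", {
  tr <- simulate_adl("ADL_STAND", 10,
                     simulation_config(noise_sd = 0, gyro_noise_sd = 0))
  expect_equal(tr$series$ax, rep(0, nrow(tr$series)))
  expect_equal(tr$series$ay, rep(0, nrow(tr$series)))
  expect_equal(tr$series$az, rep(1, nrow(tr$series)))
  expect_equal(tr$series$gx, rep(0, nrow(tr$series)))
})

test_that("series length is duration times sampling rate", {
  tr <- simulate_adl("ADL_WALK", 60, simulation_config(fs = 50))
  expect_identical(nrow(tr$series), 3000L)
})

test_that("protocol dataset has the demanded composition and is reproducible", {
  cfg <- simulation_config(seed = 5L)
  ds <- generate_protocol_dataset(2L, 3L, cfg)
  expect_length(ds, 15L)
  labs <- vapply(ds, function(tr) tr$annotation$label, character(1L))
  expect_identical(sum(labs %in% activity_labels(falls_only = TRUE)), 12L)
  nonfall <- generate_protocol_dataset(0L, 5L, cfg)
  expect_length(nonfall, 5L)
  expect_true(all(vapply(nonfall, function(tr)
    is.na(tr$annotation$t_impact), logical(1L))))
  ds2 <- generate_protocol_dataset(2L, 3L, cfg)
  expect_identical(ds, ds2)
})

test_that("GPS track scenarios honour their geometric contracts", {
  home <- c(24.95, 121.22)
  stay <- simulate_track("stay_home", home, duration = 300, seed = 4L)
  expect_lte(max(haversine_m(stay$lat, stay$lon, home[1L], home[2L])), 30)
  com <- simulate_track("commute", home, duration = 600, speed = 1, seed = 4L)
  n <- nrow(com)
  disp <- haversine_m(com$lat[n], com$lon[n], com$lat[1L], com$lon[1L])
  expect_lt(abs(disp - 600) / 600, 0.05)
  d_home <- haversine_m(com$lat, com$lon, home[1L], home[2L])
  expect_true(all(diff(d_home) > 0))
  w1 <- simulate_track("wander", home, duration = 120, seed = 8L)
  w2 <- simulate_track("wander", home, duration = 120, seed = 8L)
  expect_identical(w1, w2)
  expect_error(simulate_track("commute", home, duration = 0), "positive")
  expect_error(simulate_track("teleport", home, duration = 10), "scenario")
})

test_that("IMU CSV and annotation JSON round-trip through files", {
  tr <- simulate_fall("FALL_LEFT", simulation_config(seed = 12L))
  csv <- tempfile(fileext = ".csv")
  write_imu_csv(tr$series, csv)
  back <- read_imu_csv(csv)
  expect_equal(imu_fs(back), imu_fs(tr$series), tolerance = 1e-6)
  expect_equal(back$az, tr$series$az, tolerance = 1e-6)
  js <- tempfile(fileext = ".json")
  write_annotation_json(tr$annotation, js)
  ann <- read_annotation_json(js)
  expect_identical(ann$label, "FALL_LEFT")
  expect_equal(ann$t_impact, tr$annotation$t_impact)
  adl <- simulate_adl("ADL_STAND", 2)
  write_annotation_json(adl$annotation, js)
  expect_true(is.na(read_annotation_json(js)$t_impact))
})
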