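#' Simulation configuration
#'
#' Parameters of the four-phase synthetic fall generator. A simulated fall is
#' a quiet upright phase, a weight-loss phase whose signal vector magnitude
#' dips from 1 g to `freefall_floor` (a half-cosine), an asymmetric impact
#' spike reaching `impact_peak` (rise over the first quarter of
#' `impact_duration`, decay over the rest), and a motionless phase in the
#' final tilted orientation. White Gaussian noise is added to every channel.
#'
#' @param fs sampling rate in Hz.
#' @param pre_fall_duration quiet upright time before the fall, seconds.
#' @param freefall_duration length of the weight-loss dip, seconds.
#' @param freefall_floor target minimum SVM during weight loss, g; must be
#'   below 1 (the defining property of the weight-loss phase).
#' @param impact_peak peak SVM at impact, g; must exceed 1.
#' @param impact_duration total length of the impact spike, seconds.
#' @param motionless_duration length of the post-impact still phase, seconds.
#' @param noise_sd accelerometer noise standard deviation, g.
#' @param gyro_noise_sd gyroscope noise standard deviation, deg/s.
#' @param final_tilt final torso inclination from vertical, degrees.
#' @param seed integer seed; every simulator call is fully seeded so that
#'   identical configurations give bit-identical series.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(fs = 50,
                              pre_fall_duration = 2,
                              freefall_duration = 0.35,
                              freefall_floor = 0.4,
                              impact_peak = 2.5,
                              impact_duration = 0.16,
                              motionless_duration = 3,
                              noise_sd = 0.03,
                              gyro_noise_sd = 0.5,
                              final_tilt = 80,
                              seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (freefall_floor >= 1) stop("freefall_floor must be below 1 g")
  if (impact_peak <= 1) stop("impact_peak must exceed 1 g")
  durs <- c(pre_fall_duration, freefall_duration, impact_duration,
            motionless_duration)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (noise_sd < 0 || gyro_noise_sd < 0) stop("noise sds must be non-negative")
  structure(list(fs = fs, pre_fall_duration = pre_fall_duration,
                 freefall_duration = freefall_duration,
                 freefall_floor = freefall_floor, impact_peak = impact_peak,
                 impact_duration = impact_duration,
                 motionless_duration = motionless_duration,
                 noise_sd = noise_sd, gyro_noise_sd = gyro_noise_sd,
                 final_tilt = final_tilt, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Ground-truth phase annotation of a simulated trial
#'
#' For fall trials, the four phase boundaries (seconds): start of weight
#' loss, impact peak, start and end of the motionless interval, satisfying
#' `t_freefall_start < t_impact < t_motionless_start < t_motionless_end`.
#' Non-fall activities carry `NA` boundaries.
#'
#' @param label an [activity_labels()] value.
#' @param t_freefall_start,t_impact,t_motionless_start,t_motionless_end phase
#'   boundaries in seconds, or `NA` for non-fall activities.
#' @return a `phase_annotation` list.
#' @export
phase_annotation <- function(label, t_freefall_start = NA_real_,
                             t_impact = NA_real_,
                             t_motionless_start = NA_real_,
                             t_motionless_end = NA_real_) {
  if (!label %in% activity_labels()) stop("unknown activity label: ", label)
  ts <- c(t_freefall_start, t_impact, t_motionless_start, t_motionless_end)
  if (all(!is.na(ts)) && any(diff(ts) <= 0))
    stop("phase boundaries must be strictly increasing")
  structure(list(label = label, t_freefall_start = t_freefall_start,
                 t_impact = t_impact, t_motionless_start = t_motionless_start,
                 t_motionless_end = t_motionless_end),
            class = "phase_annotation")
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# gravity direction (unit vector in the body frame) after tilting `tilt_deg`
# from upright toward the azimuth of `label`; left/right are mirror images
# in the lateral (y) axis, back-left/back-right combine backward pitch with
# opposite-signed roll, trip-over ends like a forward fall.
fall_direction <- function(label, tilt_deg) {
  rad <- tilt_deg * pi / 180
  s <- sin(rad); cz <- cos(rad)
  sq <- 1 / sqrt(2)
  switch(label,
    FALL_FORWARD    = c( s,        0,       cz),
    FALL_LEFT       = c( 0,       -s,       cz),
    FALL_RIGHT      = c( 0,        s,       cz),
    FALL_BACK_LEFT  = c(-s * sq,  -s * sq,  cz),
    FALL_BACK_RIGHT = c(-s * sq,   s * sq,  cz),
    TRIP_OVER       = c( s,        0,       cz),
    stop("not a fall label: ", label))
}

# axis about which the body rotates while falling toward `label`'s azimuth
fall_axis <- function(label) {
  sq <- 1 / sqrt(2)
  switch(label,
    FALL_FORWARD    = c(0, 1, 0),
    FALL_LEFT       = c(1, 0, 0),
    FALL_RIGHT      = c(-1, 0, 0),
    FALL_BACK_LEFT  = c(-sq, sq, 0),
    FALL_BACK_RIGHT = c(sq, sq, 0),
    TRIP_OVER       = c(0, 1, 0))
}

#' Simulate a fall trial
#'
#' Generates a six-axis IMU series realising, in order: a quiet phase with
#' per-sample SVM about 1 g; a weight-loss phase whose minimum SVM reaches
#' `freefall_floor` (below 1 g); an impact spike peaking at `impact_peak`
#' with a sign reversal of the SVM first difference at the peak; and a
#' motionless phase in which the gravity vector is rotated by `final_tilt`
#' degrees from upright, in the direction determined by the fall label.
#' Gyroscope channels carry the angular rate consistent with the
#' orientation change plus noise; trip-over trials additionally carry the
#' sharp pitch-rate spike of the foot catching an obstacle at fall onset.
#'
#' @param label one of the six fall values of [activity_labels()].
#' @param config a [simulation_config()].
#' @return list with elements `series` ([imu_series()]) and `annotation`
#'   ([phase_annotation()]); the annotation matches the constructed phase
#'   boundaries exactly.
#' @export
simulate_fall <- function(label, config = simulation_config()) {
  if (!is_fall_label(label))
    stop("simulate_fall requires a fall label; got ", label)
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$fs
  n_pre  <- round(config$pre_fall_duration * fs)
  n_ff   <- round(config$freefall_duration * fs)
  n_rise <- max(2L, round(0.25 * config$impact_duration * fs))
  n_dec  <- max(2L, round(0.75 * config$impact_duration * fs))
  n_mot  <- round(config$motionless_duration * fs)
  n <- n_pre + n_ff + n_rise + n_dec + n_mot
  t <- (seq_len(n) - 1L) / fs

  # piecewise SVM profile
  mag <- numeric(n)
  mag[seq_len(n_pre)] <- 1
  s_ff <- seq_len(n_ff) / n_ff
  mag[n_pre + seq_len(n_ff)] <-
    config$freefall_floor + (1 - config$freefall_floor) * (1 + cos(pi * s_ff)) / 2
  s_r <- seq_len(n_rise) / n_rise
  mag[n_pre + n_ff + seq_len(n_rise)] <-
    config$freefall_floor +
    (config$impact_peak - config$freefall_floor) * (1 - cos(pi * s_r)) / 2
  s_d <- seq_len(n_dec) / n_dec
  mag[n_pre + n_ff + n_rise + seq_len(n_dec)] <-
    1 + (config$impact_peak - 1) * (1 + cos(pi * s_d)) / 2
  mag[(n_pre + n_ff + n_rise + n_dec + 1L):n] <- 1

  # tilt progresses 0 -> 40% of final during weight loss, -> 100% by impact end
  frac <- numeric(n)
  frac[n_pre + seq_len(n_ff)] <- 0.4 * s_ff
  frac[n_pre + n_ff + seq_len(n_rise + n_dec)] <-
    0.4 + 0.6 * seq_len(n_rise + n_dec) / (n_rise + n_dec)
  frac[(n_pre + n_ff + n_rise + n_dec + 1L):n] <- 1
  tilt <- config$final_tilt * frac

  dirs <- vapply(tilt, function(a) fall_direction(label, a), numeric(3L))
  acc <- t(dirs) * mag

  axis <- fall_axis(label)
  rate <- c(0, diff(tilt)) * fs            # deg/s about the fall axis
  gyro <- outer(rate, axis)

  # the foot catching an obstacle gives a trip a sharp pitch-rate spike at
  # fall onset, absent from a plain forward fall; the accelerometer
  # contract (quiet SVM of 1 g, dip, impact) is untouched
  if (label == "TRIP_OVER") {
    idx <- n_pre + seq_len(n_ff)
    gyro[idx, 2L] <- gyro[idx, 2L] + 200 * sin(pi * s_ff)
  }

  with_seed(config$seed, {
    acc  <- acc + matrix(rnorm(3L * n, sd = config$noise_sd), n, 3L)
    gyro <- gyro + matrix(rnorm(3L * n, sd = config$gyro_noise_sd), n, 3L)
  })

  series <- imu_series(data.frame(
    t = t, ax = acc[, 1L], ay = acc[, 2L], az = acc[, 3L],
    gx = gyro[, 1L], gy = gyro[, 2L], gz = gyro[, 3L]), fs)
  ann <- phase_annotation(
    label,
    t_freefall_start  = t[n_pre + 1L],
    t_impact          = t[n_pre + n_ff + n_rise],
    t_motionless_start = t[n_pre + n_ff + n_rise + n_dec + 1L],
    t_motionless_end  = t[n] + 1 / fs)
  list(series = series, annotation = ann)
}

#' Simulate a non-fall activity of daily living
#'
#' Generates walking (periodic step oscillation), sitting down and lying
#' down (orientation changes with mild magnitude excursions but no
#' weight-loss dip below `freefall_floor` and no impact spike, the case that
#' confuses naive detectors), or quiet standing. By construction no 0.2 s
#' window has mean SVM at or below `freefall_floor` followed by a peak at or
#' above `impact_peak` within 1 s, so the fall signature is absent.
#'
#' @param label one of the ADL values of [activity_labels()].
#' @param duration series length in seconds.
#' @param config a [simulation_config()] (noise, fs and seed are used).
#' @return list with elements `series` and `annotation` (phase boundaries
#'   `NA`).
#' @export
simulate_adl <- function(label, duration = 10, config = simulation_config()) {
  if (is_fall_label(label))
    stop("simulate_adl requires a non-fall label; got ", label)
  if (!label %in% ADL_LABELS) stop("unknown activity label: ", label)
  stopifnot(inherits(config, "simulation_config"))
  if (duration <= 0) stop("duration must be positive")
  fs <- config$fs
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs

  acc <- matrix(0, n, 3L); gyro <- matrix(0, n, 3L)
  if (label == "ADL_STAND") {
    acc[, 3L] <- 1
  } else if (label == "ADL_WALK") {
    step_hz <- 2
    acc[, 3L] <- 1 + 0.3 * sin(2 * pi * step_hz * t)
    acc[, 1L] <- 0.10 * sin(2 * pi * step_hz * t + pi / 3)
    acc[, 2L] <- 0.05 * sin(2 * pi * step_hz / 2 * t)
    gyro[, 2L] <- 10 * sin(2 * pi * step_hz * t)
  } else {
    # sit-down: modest recline; lie-down: near-horizontal final posture.
    # Both change orientation without the weight-loss + impact pair.
    final_tilt <- if (label == "ADL_SIT_DOWN") 20 else 80
    trans_len <- min(2, duration / 3)
    t0 <- duration / 3
    frac <- pmin(1, pmax(0, (t - t0) / trans_len))
    frac <- (1 - cos(pi * frac)) / 2                 # smooth ease-in/out
    tilt <- final_tilt * frac
    # gentle unload/contact magnitude wobble, well inside the fall bands
    mag <- 1 - 0.25 * sin(pi * frac)^2 +
      0.35 * exp(-((t - (t0 + trans_len)) * 4)^2)
    axis_lab <- if (label == "ADL_SIT_DOWN") "FALL_FORWARD" else "FALL_LEFT"
    dirs <- vapply(tilt, function(a) fall_direction(axis_lab, a), numeric(3L))
    acc <- t(dirs) * mag
    gyro <- outer(c(0, diff(tilt)) * fs, fall_axis(axis_lab))
  }

  with_seed(config$seed, {
    acc  <- acc + matrix(rnorm(3L * n, sd = config$noise_sd), n, 3L)
    gyro <- gyro + matrix(rnorm(3L * n, sd = config$gyro_noise_sd), n, 3L)
  })

  series <- imu_series(data.frame(
    t = t, ax = acc[, 1L], ay = acc[, 2L], az = acc[, 3L],
    gx = gyro[, 1L], gy = gyro[, 2L], gz = gyro[, 3L]), fs)
  list(series = series, annotation = phase_annotation(label))
}

#' Generate the evaluation protocol trial set
#'
#' `n_per_fall_type` trials of each of the six fall situations followed by
#' `n_nonfall` non-fall ADL trials (cycling over walking, sit-down, lie-down,
#' standing). Per-trial seeds are derived deterministically from
#' `config$seed`, so the same configuration always yields bit-identical
#' series.
#'
#' @param n_per_fall_type trials per fall situation (>= 0).
#' @param n_nonfall non-fall trials (>= 0).
#' @param config a [simulation_config()].
#' @param adl_duration length of each non-fall trial in seconds.
#' @return list of trials, each `list(series, annotation)`.
#' @export
generate_protocol_dataset <- function(n_per_fall_type, n_nonfall,
                                      config = simulation_config(),
                                      adl_duration = 10) {
  if (n_per_fall_type < 0 || n_nonfall < 0) stop("counts must be non-negative")
  trials <- vector("list", 6L * n_per_fall_type + n_nonfall)
  k <- 0L
  for (lab in FALL_LABELS) {
    for (i in seq_len(n_per_fall_type)) {
      k <- k + 1L
      cfg <- config; cfg$seed <- (config$seed + 131L * k) %% .Machine$integer.max
      trials[[k]] <- simulate_fall(lab, cfg)
    }
  }
  for (i in seq_len(n_nonfall)) {
    k <- k + 1L
    cfg <- config; cfg$seed <- (config$seed + 131L * k) %% .Machine$integer.max
    lab <- ADL_LABELS[((i - 1L) %% length(ADL_LABELS)) + 1L]
    trials[[k]] <- simulate_adl(lab, adl_duration, cfg)
  }
  trials
}

#' Write and read a phase-annotation sidecar JSON
#'
#' `{label, t_freefall_start, t_impact, t_motionless_start,
#' t_motionless_end}` with `null` boundaries for non-fall activities.
#'
#' @param annotation a [phase_annotation()].
#' @param path file path.
#' @return `read_annotation_json` returns a [phase_annotation()].
#' @export
write_annotation_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "phase_annotation"))
  x <- unclass(annotation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  phase_annotation(x$label, num(x$t_freefall_start), num(x$t_impact),
                   num(x$t_motionless_start), num(x$t_motionless_end))
}

EARTH_RADIUS_M <- 6371000
M_PER_DEG_LAT <- pi * EARTH_RADIUS_M / 180

#' Simulate a GPS track
#'
#' Fixture generator for the location analytics: `stay_home` jitters within
#' 30 m of `home`; `commute` moves away from home at constant `speed` along
#' a fixed bearing; `wander` is a seeded random walk at `speed`. Points are
#' emitted at 1 Hz epoch-second timestamps.
#'
#' @param scenario one of `"stay_home"`, `"commute"`, `"wander"`.
#' @param home `c(lat, lon)` in WGS84 decimal degrees.
#' @param duration track length in seconds (> 0).
#' @param speed movement speed in m/s.
#' @param seed integer seed.
#' @param wearer_id wearer identifier attached to the track.
#' @return a [geo_track()].
#' @export
simulate_track <- function(scenario, home = c(24.95, 121.22), duration = 600,
                           speed = 1, seed = 1L, wearer_id = "wearer") {
  if (duration <= 0) stop("duration must be positive")
  if (!scenario %in% c("stay_home", "commute", "wander"))
    stop("unknown scenario: ", scenario)
  n <- floor(duration) + 1L
  m_lat <- M_PER_DEG_LAT
  m_lon <- M_PER_DEG_LAT * cos(home[1L] * pi / 180)
  xy <- with_seed(seed, {
    if (scenario == "stay_home") {
      r <- 20 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    } else if (scenario == "commute") {
      bearing <- runif(1L, 0, 2 * pi)
      d <- (seq_len(n) - 1L) * speed
      cbind(d * cos(bearing), d * sin(bearing))
    } else {
      th <- runif(n - 1L, 0, 2 * pi)
      rbind(c(0, 0), cbind(cumsum(speed * cos(th)), cumsum(speed * sin(th))))
    }
  })
  geo_track(data.frame(t = seq_len(n) - 1L,
                       lat = home[1L] + xy[, 2L] / m_lat,
                       lon = home[2L] + xy[, 1L] / m_lon),
            wearer_id = wearer_id)
}
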