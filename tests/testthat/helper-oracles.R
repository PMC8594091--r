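# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with naive per-sample loops (or direct filter calls)
# so they share no code path with the package implementations they check.

brute_svm <- function(df) {
  out <- numeric(nrow(df))
  for (i in seq_len(nrow(df)))
    out[i] <- sqrt(df$ax[i]^2 + df$ay[i]^2 + df$az[i]^2)
  out
}

brute_sma <- function(df) {
  total <- 0
  for (i in seq_len(nrow(df)))
    total <- total + abs(df$ax[i]) + abs(df$ay[i]) + abs(df$az[i])
  total / nrow(df)
}

# literal per-sample re-implementation of the documented four-stage state
# machine; the gravity estimate is the shared published preprocessing step
# (the scan over it is what this oracle re-derives independently)
brute_detect <- function(series, th = detector_thresholds(),
                         gravity_cutoff = 1.0) {
  fs <- imu_fs(series)
  df <- as.data.frame(series)
  n <- nrow(df)
  tvec <- df$t
  v <- brute_svm(df)
  gsep <- separate_gravity(series, cutoff = gravity_cutoff)
  grav <- cbind(gsep$gravity$ax, gsep$gravity$ay, gsep$gravity$az)
  bodymag <- numeric(n)
  for (i in seq_len(n))
    bodymag[i] <- abs(df$ax[i] - grav[i, 1]) + abs(df$ay[i] - grav[i, 2]) +
      abs(df$az[i] - grav[i, 3])
  m <- round(th$motionless_window * fs)
  roll <- function(k) mean(bodymag[k:(k + m - 1L)])

  events <- NULL
  i <- 1L
  while (i <= n) {
    if (!(v[i] < th$freefall_g)) { i <- i + 1L; next }
    i_ff <- i
    j_max <- i_ff
    for (j in i_ff:n) if (tvec[j] - tvec[i_ff] <= th$max_gap) j_max <- j
    j <- NA_integer_
    if (j_max > i_ff) for (jj in (i_ff + 1L):j_max) {
      if (v[jj] > th$impact_g) { j <- jj; break }
    }
    if (is.na(j)) { i <- j_max + 1L; next }
    while (j < n && v[j + 1L] >= v[j]) j <- j + 1L
    if (j == n) { i <- j_max + 1L; next }
    k_deadline <- j
    for (k in j:n) if (tvec[k] - tvec[j] <= th$motionless_deadline)
      k_deadline <- k
    conf <- NA_integer_
    for (k in j:min(k_deadline, n - m + 1L)) {
      if (roll(k) < th$motionless_sma_g) { conf <- k; break }
    }
    if (is.na(conf)) { i <- k_deadline + 1L; next }
    k_end <- conf + m - 1L
    pre_idx <- which(tvec >= tvec[i_ff] - 1 & tvec < tvec[i_ff])
    if (length(pre_idx) == 0L) pre_idx <- i_ff
    post_idx <- which(tvec >= tvec[k_end] & tvec <= tvec[k_end] + 0.5)
    a <- colMeans(grav[pre_idx, , drop = FALSE])
    b <- colMeans(grav[post_idx, , drop = FALSE])
    ang <- acos(min(1, max(-1, sum(a * b) /
                             (sqrt(sum(a^2)) * sqrt(sum(b^2)))))) * 180 / pi
    events <- rbind(events, data.frame(
      t_freefall = tvec[i_ff], t_impact = tvec[j],
      t_motionless_confirmed = tvec[k_end], orientation_change = ang))
    i <- k_end + 1L
  }
  events
}

# classifier fixture: a 128-sample window covering free fall, impact and
# early motionless of one simulated fall
make_fall_window <- function(label, seed, len = 128L) {
  tr <- simulate_fall(label, simulation_config(seed = seed))
  s <- tr$series
  end <- which.min(abs(s$t - (tr$annotation$t_motionless_start + 1)))
  df <- as.data.frame(s)
  df$svm <- svm_g(s)
  rows <- df[(end - len + 1L):end, ]
  feature_window(rows, rows$t[1L], rows$t[len], label = label)
}

separable_dataset <- function(n_per_class = 10L) {
  wins <- list()
  k <- 0L
  for (lab in activity_labels(falls_only = TRUE)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      wins[[k]] <- make_fall_window(lab, seed = 1000L + k)
    }
  }
  window_dataset(wins)
}

random_device_message <- function(seed) {
  set.seed(seed)
  device_message(
    member_id = paste0("m-", sample.int(9999L, 1L)),
    imei = paste(sample(0:9, 15L, replace = TRUE), collapse = ""),
    sn = paste0("SN", sample.int(999L, 1L)),
    t = 1700000000 + sample.int(86400L, 1L),
    kind = sample(c("MEASUREMENT", "ALARM", "SOS", "BATTERY_LOW"), 1L),
    gps = if (runif(1) < 0.5) c(runif(1, -90, 90), runif(1, -180, 180)),
    payload = setNames(as.list(round(runif(3L, 0, 200), 3L)),
                       c("hr", "spo2", "steps")))
}

# annotated alarm records built from simulated falls with a chosen impact peak
make_alarm_record <- function(impact_peak, seed, annotation,
                              fall_class = NULL) {
  tr <- simulate_fall("FALL_FORWARD",
                      simulation_config(seed = seed,
                                        impact_peak = impact_peak))
  rec <- alarm_record("m1", tr$annotation$t_impact,
                      noise_filter(tr$series))
  annotate_alarm(rec, annotation, "caregiver", fall_class = fall_class)
}
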