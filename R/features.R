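#' Signal vector magnitude (SVM)
#'
#' Euclidean norm of the tri-axial acceleration vector,
#' `sqrt(ax^2 + ay^2 + az^2)`, in g. At rest the magnitude is 1 g; during the
#' weight-loss phase of a fall it drops below 1 g and at impact it spikes
#' above it, which is what the threshold detector keys on. Vectorised.
#'
#' @param ax,ay,az acceleration components in g, or `ax` may be an
#'   [imu_series()] (then `ay`/`az` are ignored).
#' @return non-negative numeric vector of magnitudes in g.
#' @export
svm_g <- function(ax, ay = NULL, az = NULL) {
  if (inherits(ax, "imu_series") || (is.data.frame(ax) && all(c("ax", "ay", "az") %in% names(ax)))) {
    ay <- ax$ay; az <- ax$az; ax <- ax$ax
  }
  if (any(!is.finite(ax)) || any(!is.finite(ay)) || any(!is.finite(az)))
    stop("svm_g requires finite acceleration channels")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Signal magnitude area (SMA)
#'
#' Time-average over a window of the summed absolute tri-axial accelerations,
#' the discrete (rectangle-rule) form of the continuous integral
#' `(1/t) * [ int |x| dt + int |y| dt + int |z| dt ]`. Applied to the body
#' (gravity-removed) component it measures motion intensity and is the
#' motionless-phase statistic of the fall detector.
#'
#' @param window a [feature_window()], an [imu_series()], or a data frame
#'   with `ax, ay, az` columns, all in g.
#' @return mean summed absolute acceleration in g.
#' @export
sma_g <- function(window) {
  if (inherits(window, "feature_window")) window <- window$data
  if (is.matrix(window)) window <- as.data.frame(window)
  if (!all(c("ax", "ay", "az") %in% names(window)))
    stop("sma_g requires ax, ay, az columns")
  if (nrow(window) == 0L) stop("sma_g of an empty window is undefined")
  mean(abs(window$ax) + abs(window$ay) + abs(window$az))
}

#' Tilt angles of the acceleration vector
#'
#' Inclination angles (degrees) of the measured acceleration relative to the
#' body axes: `rho = atan(ax / sqrt(ay^2 + az^2))`,
#' `phi = atan(ay / sqrt(ax^2 + az^2))`, and the inclination from vertical
#' `theta = atan2(sqrt(ax^2 + ay^2), az)`. The atan2 form keeps `theta`
#' well defined for vertical and inverted postures: an upside-down wearer
#' (`az < 0`) maps to `theta > 90` degrees. Vectorised.
#'
#' @param ax,ay,az acceleration components in g, or `ax` an [imu_series()].
#' @return data frame with columns `rho`, `phi`, `theta` in degrees
#'   (`rho`, `phi` in \[-90, 90\]; `theta` in \[0, 180\]).
#' @export
tilt_angles <- function(ax, ay = NULL, az = NULL) {
  if (inherits(ax, "imu_series") || (is.data.frame(ax) && all(c("ax", "ay", "az") %in% names(ax)))) {
    ay <- ax$ay; az <- ax$az; ax <- ax$ax
  }
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(mag == 0))
    stop("tilt angles are undefined for a zero-magnitude acceleration sample")
  deg <- 180 / pi
  data.frame(
    rho   = atan2(ax, sqrt(ay^2 + az^2)) * deg,
    phi   = atan2(ay, sqrt(ax^2 + az^2)) * deg,
    theta = atan2(sqrt(ax^2 + ay^2), az) * deg
  )
}

# zero-phase order-3 Butterworth low-pass of one channel. The signal is
# anchored at its mean (so a constant passes through exactly) and padded by
# odd extension before filtfilt to suppress the zero-initial-state edge
# transient of the forward/backward passes.
butter_lp <- function(x, fs, cutoff, order = 3L) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  mu <- mean(x)
  xc <- x - mu
  n <- length(xc)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff))
  if (pad > 0L) {
    head_ext <- 2 * xc[1L] - xc[(pad + 1L):2L]
    tail_ext <- 2 * xc[n] - xc[(n - 1L):(n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(head_ext, xc, tail_ext)))
    y <- y[(pad + 1L):(pad + n)]
  } else {
    y <- as.numeric(signal::filtfilt(bf, xc))
  }
  y + mu
}

#' Noise-filter an IMU series
#'
#' Per-channel median filter (kernel 3) followed by a zero-phase low-pass
#' Butterworth filter (order 3, default 20 Hz cutoff). The median stage
#' removes single-sample spikes; the low-pass removes wide-band sensor noise
#' above the band of human movement. Length is preserved and a constant
#' series passes through unchanged.
#'
#' @param series an [imu_series()] of at least 9 samples.
#' @param cutoff low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param order Butterworth order.
#' @return a filtered [imu_series()] of identical length and timing.
#' @export
noise_filter <- function(series, cutoff = 20, order = 3L) {
  stopifnot(inherits(series, "imu_series"))
  fs <- imu_fs(series)
  if (nrow(series) < 9L) stop("noise_filter requires at least 9 samples")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist rate fs/2")
  out <- as.data.frame(series)
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) {
    x <- runmed(out[[ch]], k = 3L, endrule = "keep")
    out[[ch]] <- butter_lp(x, fs, cutoff, order)
  }
  new_imu_series(out, fs)
}

#' Separate gravitational and body-motion acceleration
#'
#' The measured acceleration has a gravitational and a body-motion component.
#' The gravity estimate is a zero-phase low-pass (Butterworth order 3,
#' default 0.3 Hz cutoff) of each acceleration channel; the body component is
#' the per-sample difference, so `gravity + body = original` exactly.
#' Gyroscope channels are copied to the gravity series and zeroed in the body
#' series.
#'
#' @param series a (filtered) [imu_series()].
#' @param cutoff gravity low-pass cutoff in Hz; must be below Nyquist.
#' @return list with elements `gravity` and `body`, both [imu_series()].
#' @export
separate_gravity <- function(series, cutoff = 0.3) {
  stopifnot(inherits(series, "imu_series"))
  fs <- imu_fs(series)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist rate fs/2")
  grav <- as.data.frame(series)
  body <- as.data.frame(series)
  for (ch in c("ax", "ay", "az")) {
    g <- butter_lp(grav[[ch]], fs, cutoff)
    body[[ch]] <- grav[[ch]] - g
    grav[[ch]] <- g
  }
  for (ch in c("gx", "gy", "gz")) body[[ch]] <- 0
  list(gravity = new_imu_series(grav, fs), body = new_imu_series(body, fs))
}

#' Sliding-window configuration
#'
#' Fixed-width sliding windows are the unit fed to the classifier. The
#' default 2.56 s width with 50% overlap gives 128-sample windows at 50 Hz,
#' the standard human-activity-recognition convention.
#'
#' @param width window width in seconds (> 0).
#' @param overlap fraction of the window shared with its successor, in
#'   \[0, 1).
#' @return a `window_config` list.
#' @export
window_config <- function(width = 2.56, overlap = 0.5) {
  if (width <= 0) stop("width must be positive")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(width = width, overlap = overlap), class = "window_config")
}

#' A fixed-width feature window
#'
#' One classifier input: a `round(width * fs)`-row matrix of the six raw
#' channels plus the derived per-sample SVM, with its time extent and an
#' optional activity label.
#'
#' @param data matrix or data frame with columns
#'   `ax, ay, az, gx, gy, gz, svm`.
#' @param t_start,t_end window extent in seconds.
#' @param label optional [activity_labels()] value.
#' @return a `feature_window` list.
#' @export
feature_window <- function(data, t_start, t_end, label = NA_character_) {
  data <- as.matrix(as.data.frame(data)[c("ax", "ay", "az", "gx", "gy", "gz", "svm")])
  if (!is.na(label) && !label %in% activity_labels())
    stop("unknown activity label: ", label)
  structure(list(data = data, t_start = t_start, t_end = t_end, label = label),
            class = "feature_window")
}

#' Cut an IMU series into fixed-width sliding windows
#'
#' Windows have identical sample counts `round(width * fs)` and start every
#' `width * (1 - overlap)` seconds; a trailing partial window is dropped. A
#' series shorter than one window yields an empty list.
#'
#' @param series an [imu_series()].
#' @param config a [window_config()].
#' @param label optional label attached to every window.
#' @return list of [feature_window()] objects.
#' @export
sliding_windows <- function(series, config = window_config(),
                            label = NA_character_) {
  stopifnot(inherits(series, "imu_series"))
  fs <- imu_fs(series)
  n <- round(config$width * fs)
  stride <- max(1L, round(config$width * (1 - config$overlap) * fs))
  len <- nrow(series)
  if (len < n) return(list())
  starts <- seq.int(1L, len - n + 1L, by = stride)
  df <- as.data.frame(series)
  df$svm <- svm_g(df$ax, df$ay, df$az)
  lapply(starts, function(i) {
    rows <- df[i:(i + n - 1L), ]
    feature_window(rows, t_start = rows$t[1L], t_end = rows$t[n], label = label)
  })
}

#' Serialise feature windows to a flat CSV
#'
#' One row per window: `window_id`, `t_start`, `label`, then the window
#' matrix flattened row-major as `<channel>_<sample>` columns.
#'
#' @param windows list of [feature_window()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  if (length(windows) == 0L) {
    write.csv(data.frame(window_id = integer(), t_start = numeric(),
                         label = character()), path, row.names = FALSE)
    return(invisible(path))
  }
  flat <- do.call(rbind, lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    v <- as.vector(t(w$data))
    names(v) <- paste0(rep(colnames(w$data), nrow(w$data)), "_",
                       rep(seq_len(nrow(w$data)), each = ncol(w$data)))
    cbind(data.frame(window_id = i, t_start = w$t_start,
                     label = w$label, stringsAsFactors = FALSE),
          as.data.frame(t(v)))
  }))
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
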