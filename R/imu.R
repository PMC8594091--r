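#' Six-axis inertial series
#'
#' An `imu_series` is a data frame with columns `t` (seconds from series
#' start), `ax`, `ay`, `az` (linear acceleration in g, gravity included) and
#' `gx`, `gy`, `gz` (angular velocity in deg/s), sampled uniformly at `fs` Hz.
#' Timestamps must be strictly increasing and uniformly spaced at `1/fs`
#' within 1e-9 s.
#'
#' @param df data frame with columns `t, ax, ay, az, gx, gy, gz`.
#' @param fs sampling rate in Hz (> 0).
#' @return an object of class `imu_series` (a data frame).
#' @export
imu_series <- function(df, fs) {
  cols <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!is.data.frame(df) || !all(cols %in% names(df)))
    stop("imu_series requires columns t, ax, ay, az, gx, gy, gz")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  df <- as.data.frame(df)[cols]
  if (nrow(df) == 0L) stop("imu_series must contain at least one sample")
  if (any(!is.finite(as.matrix(df))))
    stop("all channels must be finite")
  if (df$t[1L] < 0) stop("timestamps must be non-negative")
  if (nrow(df) > 1L) {
    dt <- diff(df$t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / fs) > 1e-9))
      stop("sample spacing must be uniform at 1/fs within 1e-9 s")
  }
  structure(df, fs = fs, class = c("imu_series", "data.frame"))
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> %d samples at %g Hz (%.2f s)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  print.data.frame(head(as.data.frame(x), 4L))
  invisible(x)
}

#' Sampling rate of an IMU series
#' @param series an [imu_series()].
#' @return sampling rate in Hz.
#' @export
imu_fs <- function(series) {
  fs <- attr(series, "fs")
  if (is.null(fs)) stop("not an imu_series: missing fs attribute")
  fs
}

# internal fast constructor: trusted input, skips revalidation
new_imu_series <- function(df, fs) {
  structure(as.data.frame(df), fs = fs,
            class = c("imu_series", "data.frame"))
}

#' Read and write the IMU CSV interchange format
#'
#' Plain CSV with header `t,ax,ay,az,gx,gy,gz`, one row per sample, `t` in
#' seconds (written with 6 decimals), accelerations in g, angular rates in
#' deg/s. The sampling rate is recovered from the median timestamp spacing
#' unless given.
#'
#' @param series an [imu_series()].
#' @param path file path.
#' @param fs optional sampling rate override when reading.
#' @return `read_imu_csv` returns an [imu_series()]; `write_imu_csv`
#'   returns `path` invisibly.
#' @export
write_imu_csv <- function(series, path) {
  stopifnot(inherits(series, "imu_series"))
  df <- as.data.frame(series)
  df$t <- sprintf("%.6f", df$t)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, fs = NULL) {
  df <- read.csv(path)
  if (is.null(fs)) {
    if (nrow(df) < 2L) stop("cannot infer fs from a single-row CSV; pass fs")
    fs <- 1 / stats::median(diff(df$t))
  }
  # re-grid timestamps: 6-decimal text can violate the 1e-9 uniformity bound
  df$t <- df$t[1L] + seq_len(nrow(df)) / fs - 1 / fs
  imu_series(df, fs)
}
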