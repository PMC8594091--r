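#' Detector thresholds
#'
#' Parameters of the four-stage threshold fall detector. A fall is
#' confirmed when, in order: (1) the per-sample SVM drops below `freefall_g`
#' (weight loss — the resultant acceleration of a genuine fall dips below
#' 1 g); (2) within `max_gap` seconds the SVM exceeds `impact_g` and the
#' first difference of the SVM reverses sign (the impact spike); (3) the
#' body-component signal magnitude area stays below `motionless_sma_g` over
#' a `motionless_window`-second window beginning within
#' `motionless_deadline` seconds of impact; (4) the tilt of the gravity
#' vector after the motionless window differs from its pre-fall tilt by at
#' least `orientation_delta_deg`, which marks the event severe. These are
#' the per-user quantities the adaptive loop re-derives from annotated
#' alarm records.
#'
#' @param freefall_g stage-1 SVM trigger in g, in (0, 1).
#' @param impact_g stage-2 SVM trigger in g, above 1.
#' @param max_gap free-fall to impact deadline, seconds.
#' @param motionless_window stage-3 window length, seconds.
#' @param motionless_sma_g body-component SMA ceiling, g.
#' @param orientation_delta_deg stage-4 severity threshold, degrees, in
#'   (0, 180\].
#' @param motionless_deadline latest allowed start of the motionless window
#'   after impact, seconds.
#' @return a `detector_thresholds` list.
#' @export
detector_thresholds <- function(freefall_g = 0.75, impact_g = 2.0,
                                max_gap = 1.0, motionless_window = 2.0,
                                motionless_sma_g = 0.2,
                                orientation_delta_deg = 45,
                                motionless_deadline = 5.0) {
  if (!(freefall_g > 0 && freefall_g < 1 && impact_g > 1))
    stop("need 0 < freefall_g < 1 < impact_g")
  if (any(c(max_gap, motionless_window, motionless_deadline) <= 0))
    stop("durations must be positive")
  if (orientation_delta_deg <= 0 || orientation_delta_deg > 180)
    stop("orientation_delta_deg must be in (0, 180]")
  structure(list(freefall_g = freefall_g, impact_g = impact_g,
                 max_gap = max_gap, motionless_window = motionless_window,
                 motionless_sma_g = motionless_sma_g,
                 orientation_delta_deg = orientation_delta_deg,
                 motionless_deadline = motionless_deadline),
            class = "detector_thresholds")
}

#' Read and write detector thresholds as JSON
#'
#' The JSON document mirrors the [detector_thresholds()] field names
#' exactly; this is the payload the server pushes back to the front-end
#' device after adaptive re-derivation.
#'
#' @param thresholds a [detector_thresholds()].
#' @param path file path.
#' @return `read_thresholds_json` returns a [detector_thresholds()].
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "detector_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  x <- jsonlite::read_json(path)
  do.call(detector_thresholds, lapply(x, as.numeric))
}

# angle in degrees between two 3-vectors
vec_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  acos(pmin(1, pmax(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Run the four-stage threshold fall detector
#'
#' Scans a filtered IMU series with the state machine described in
#' [detector_thresholds()]. From IDLE, an SVM sample below `freefall_g`
#' opens a free-fall episode; if the SVM does not exceed `impact_g` (with a
#' subsequent decrease, the sign reversal of the first difference) within
#' `max_gap` seconds, the machine returns to IDLE at the first sample after
#' the deadline. After an impact peak, the first `motionless_window` whose
#' body-component SMA is below `motionless_sma_g`, starting within
#' `motionless_deadline` of the peak, confirms the event at the window's
#' end; otherwise the machine resets at the first sample after that
#' deadline. The orientation change compares the mean gravity vector over
#' the second before free fall with the half second after confirmation;
#' `severe` is `TRUE` when it reaches `orientation_delta_deg`. Events are
#' disjoint in time; scanning resumes after each confirmed event.
#'
#' @param series a noise-filtered [imu_series()] (NaN samples are an error).
#' @param thresholds a [detector_thresholds()].
#' @param gravity_cutoff low-pass cutoff (Hz) of the gravity estimate used
#'   for the motionless and orientation stages; 1 Hz tracks the abrupt
#'   orientation change of a fall closely enough that the post-impact body
#'   residual decays within the motionless deadline.
#' @return data frame of fall events with columns `t_freefall`, `t_impact`,
#'   `t_motionless_confirmed`, `orientation_change`, `severe`,
#'   `predicted_class` (`NA` until attributed by a classifier).
#' @export
detect_falls <- function(series, thresholds = detector_thresholds(),
                         gravity_cutoff = 1.0) {
  stopifnot(inherits(series, "imu_series"),
            inherits(thresholds, "detector_thresholds"))
  if (any(!is.finite(as.matrix(as.data.frame(series)))))
    stop("series contains non-finite samples; filter it first")
  fs <- imu_fs(series)
  n <- nrow(series)
  tvec <- series$t
  v <- svm_g(series)
  sep <- separate_gravity(series, cutoff = gravity_cutoff)
  grav <- as.matrix(as.data.frame(sep$gravity)[c("ax", "ay", "az")])
  bodymag <- abs(sep$body$ax) + abs(sep$body$ay) + abs(sep$body$az)
  m <- round(thresholds$motionless_window * fs)
  # rolling body SMA of windows starting at each sample
  cs <- cumsum(c(0, bodymag))
  n_roll <- n - m + 1L
  roll_sma <- if (n_roll >= 1L) (cs[(m + 1L):(n + 1L)] - cs[1:n_roll]) / m
              else numeric(0)

  events <- list()
  i <- 1L
  while (i <= n) {
    if (!(v[i] < thresholds$freefall_g)) { i <- i + 1L; next }
    i_ff <- i
    j_max <- max(which(tvec - tvec[i_ff] <= thresholds$max_gap))
    hits <- which(v[(i_ff + 1L):j_max] > thresholds$impact_g)
    if (length(hits) == 0L) { i <- j_max + 1L; next }
    j <- i_ff + hits[1L]
    while (j < n && v[j + 1L] >= v[j]) j <- j + 1L   # advance to the peak
    if (j == n) { i <- j_max + 1L; next }            # no reversal observed
    # stage 3: motionless confirmation
    k_first <- j
    k_last <- max(which(tvec - tvec[j] <= thresholds$motionless_deadline))
    k_last <- min(k_last, n_roll)
    conf <- NA_integer_
    if (k_last >= k_first) {
      ok <- which(roll_sma[k_first:k_last] < thresholds$motionless_sma_g)
      if (length(ok)) conf <- k_first + ok[1L] - 1L
    }
    if (is.na(conf)) {
      i <- max(which(tvec - tvec[j] <= thresholds$motionless_deadline)) + 1L
      next
    }
    k_end <- conf + m - 1L
    # stage 4: orientation change pre free fall vs post motionless
    pre_idx <- which(tvec >= tvec[i_ff] - 1 & tvec < tvec[i_ff])
    if (length(pre_idx) == 0L) pre_idx <- i_ff
    post_idx <- which(tvec >= tvec[k_end] & tvec <= tvec[k_end] + 0.5)
    ang <- vec_angle_deg(colMeans(grav[pre_idx, , drop = FALSE]),
                         colMeans(grav[post_idx, , drop = FALSE]))
    events[[length(events) + 1L]] <- data.frame(
      t_freefall = tvec[i_ff], t_impact = tvec[j],
      t_motionless_confirmed = tvec[k_end], orientation_change = ang,
      severe = ang >= thresholds$orientation_delta_deg,
      predicted_class = NA_character_, stringsAsFactors = FALSE)
    i <- k_end + 1L
  }
  if (length(events) == 0L)
    return(data.frame(t_freefall = numeric(), t_impact = numeric(),
                      t_motionless_confirmed = numeric(),
                      orientation_change = numeric(), severe = logical(),
                      predicted_class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Derive per-user thresholds from annotated alarm records
#'
#' The server-side adaptive loop: a grid search over
#' `(freefall_g, impact_g)` candidate pairs (20 x 20 by default, plus the
#' base pair) evaluated by re-running [detect_falls()] on every annotated
#' alarm record's IMU window. The objective is the number of false-alarm
#' records that still trigger plus the number of true-alarm records that no
#' longer trigger; ties are broken toward the base thresholds. With no
#' records the base is returned verbatim. The result is the payload pushed
#' back to the front-end device ([write_thresholds_json()]).
#'
#' @param records list of [alarm_record()] objects, all annotated
#'   TRUE_ALARM or FALSE_ALARM.
#' @param base the current [detector_thresholds()].
#' @param model optional [train_classifier()] model; when supplied it is
#'   used only to attach fall-type attributions to record events, never in
#'   the threshold objective.
#' @param grid_n candidates per axis.
#' @param freefall_range,impact_range inclusive grid bounds in g.
#' @return a [detector_thresholds()] satisfying the type invariants.
#' @export
derive_thresholds <- function(records, base = detector_thresholds(),
                              model = NULL, grid_n = 20L,
                              freefall_range = c(0.3, 0.95),
                              impact_range = c(1.2, 3.0)) {
  stopifnot(inherits(base, "detector_thresholds"))
  if (length(records) == 0L) return(base)
  ann <- vapply(records, function(r) r$annotation, character(1L))
  if (any(ann == "UNREVIEWED"))
    stop("derive_thresholds requires annotated records; found UNREVIEWED")
  ff_grid <- sort(unique(c(seq(freefall_range[1L], freefall_range[2L],
                               length.out = grid_n), base$freefall_g)))
  ig_grid <- sort(unique(c(seq(impact_range[1L], impact_range[2L],
                               length.out = grid_n), base$impact_g)))
  is_true <- ann == "TRUE_ALARM"
  best <- NULL
  for (ff in ff_grid) {
    for (ig in ig_grid) {
      th <- base; th$freefall_g <- ff; th$impact_g <- ig
      fired <- vapply(records, function(r)
        nrow(detect_falls(r$imu_window, th)) > 0L, logical(1L))
      obj <- sum(fired & !is_true) + sum(!fired & is_true)
      dist <- abs(ff - base$freefall_g) + abs(ig - base$impact_g)
      if (is.null(best) || obj < best$obj ||
          (obj == best$obj && dist < best$dist)) {
        best <- list(ff = ff, ig = ig, obj = obj, dist = dist)
      }
    }
  }
  out <- base
  out$freefall_g <- best$ff
  out$impact_g <- best$ig
  out
}

#' Attribute fall types to detected events with a trained classifier
#'
#' For each event, the classifier window ending at the event's motionless
#' confirmation is scored with [predict_proba()] and the highest-probability
#' fall type is written to `predicted_class`.
#'
#' @param events event data frame from [detect_falls()].
#' @param series the [imu_series()] the events were detected in.
#' @param model a [train_classifier()] model.
#' @return the events data frame with `predicted_class` filled in.
#' @export
attribute_fall_types <- function(events, series, model) {
  stopifnot(inherits(series, "imu_series"))
  if (nrow(events) == 0L) return(events)
  fs <- imu_fs(series)
  len <- model$window_len
  df <- as.data.frame(series)
  df$svm <- svm_g(series)
  for (e in seq_len(nrow(events))) {
    end <- which.min(abs(series$t - events$t_motionless_confirmed[e]))
    start <- max(1L, end - len + 1L)
    rows <- df[start:(start + len - 1L), ]
    w <- feature_window(rows, rows$t[1L], rows$t[len])
    p <- predict_proba(model, w)
    events$predicted_class[e] <- names(p)[which.max(p)]
  }
  events
}
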