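MESSAGE_KINDS <- c("MEASUREMENT", "ALARM", "SOS", "BATTERY_LOW")

# identity-document keys the platform must never carry; membership
# identification uses the opaque member_id (or its alias) only
FORBIDDEN_KEYS <- c("national_id", "identity_card", "certificate_number",
                    "personal_id", "id_card", "passport_number")

MESSAGE_KEYS <- c("member_id", "member_alias", "imei", "sn", "t", "kind",
                  "gps", "payload")

#' Construct a device message
#'
#' The device-to-server data unit: membership identification (an opaque
#' `member_id`, the primary key under which measurements are archived, with
#' an optional short alias), device identifiers, a timestamp, a message
#' kind, an optional GPS point and a measurement payload. Identity-document
#' fields (certificate numbers, national IDs and the like) are rejected
#' outright — the platform never transmits personal identity.
#'
#' @param member_id non-empty membership identification string.
#' @param imei,sn device identifiers.
#' @param t timestamp, `POSIXct` or epoch seconds.
#' @param kind one of `MEASUREMENT`, `ALARM`, `SOS`, `BATTERY_LOW`.
#' @param gps optional `c(lat, lon)`.
#' @param payload named list of measurement values.
#' @param member_alias optional member simple-identification alias.
#' @return a `device_message` list.
#' @export
device_message <- function(member_id, imei = "", sn = "",
                           t = Sys.time(), kind = "MEASUREMENT",
                           gps = NULL, payload = list(),
                           member_alias = NULL) {
  if (!is.character(member_id) || length(member_id) != 1L ||
      !nzchar(member_id))
    stop("member_id must be a non-empty string")
  if (!kind %in% MESSAGE_KINDS)
    stop("kind must be one of ", paste(MESSAGE_KINDS, collapse = ", "))
  bad <- intersect(names(payload), FORBIDDEN_KEYS)
  if (length(bad))
    stop("personal identity fields are not transmitted: ",
         paste(bad, collapse = ", "))
  if (!is.null(gps)) {
    gps <- c(lat = as.numeric(gps[[1L]]), lon = as.numeric(gps[[2L]]))
    if (abs(gps[["lat"]]) > 90 || abs(gps[["lon"]]) > 180)
      stop("gps coordinates out of WGS84 range")
  }
  if (inherits(t, "POSIXct")) t <- as.numeric(t)
  structure(list(member_id = member_id, member_alias = member_alias,
                 imei = imei, sn = sn, t = as.numeric(t), kind = kind,
                 gps = gps, payload = payload),
            class = "device_message")
}

#' Encode a device message as canonical JSON
#'
#' Canonical form: keys sorted alphabetically, UTF-8, ISO-8601 UTC
#' timestamp, absent optional fields (gps, alias) omitted entirely. The
#' encoding round-trips losslessly through [decode_message()].
#'
#' @param msg a [device_message()].
#' @return a single JSON string.
#' @export
encode_message <- function(msg) {
  stopifnot(inherits(msg, "device_message"))
  x <- list(imei = msg$imei, kind = msg$kind, member_id = msg$member_id,
            payload = msg$payload, sn = msg$sn,
            t = format(as.POSIXct(msg$t, origin = "1970-01-01", tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%OS3Z"))
  if (!is.null(msg$member_alias)) x$member_alias <- msg$member_alias
  if (!is.null(msg$gps)) x$gps <- list(lat = msg$gps[["lat"]],
                                       lon = msg$gps[["lon"]])
  x <- x[order(names(x))]
  bad <- intersect(names(x$payload), FORBIDDEN_KEYS)
  if (length(bad))
    stop("personal identity fields are not transmitted: ",
         paste(bad, collapse = ", "))
  if (length(x$payload)) x$payload <- x$payload[order(names(x$payload))]
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Decode and validate a device-message JSON
#'
#' Strict schema validation: unknown top-level keys are rejected, the kind
#' must be from the enumeration, `member_id` must be present and non-empty,
#' and identity-document keys anywhere in the message are an error. The
#' error message lists every offending field.
#'
#' @param text a JSON string produced by [encode_message()] or a compatible
#'   source.
#' @return a [device_message()].
#' @export
decode_message <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e) stop("malformed JSON: ",
                                         conditionMessage(e)))
  problems <- character()
  unknown <- setdiff(names(x), MESSAGE_KEYS)
  forbidden <- intersect(c(names(x), names(x$payload)), FORBIDDEN_KEYS)
  if (length(forbidden))
    problems <- c(problems, paste0("forbidden identity field(s): ",
                                   paste(forbidden, collapse = ", ")))
  unknown <- setdiff(unknown, forbidden)
  if (length(unknown))
    problems <- c(problems, paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))
  if (is.null(x$member_id) || !nzchar(x$member_id))
    problems <- c(problems, "member_id missing or empty")
  if (is.null(x$kind) || !x$kind %in% MESSAGE_KINDS)
    problems <- c(problems, "kind missing or not in the enumeration")
  if (length(problems))
    stop("invalid device message: ", paste(problems, collapse = "; "))
  t_num <- if (is.character(x$t))
    as.numeric(as.POSIXct(x$t, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  else as.numeric(x$t)
  gps <- if (!is.null(x$gps)) c(x$gps$lat, x$gps$lon)
  device_message(member_id = x$member_id, imei = x$imei %||% "",
                 sn = x$sn %||% "", t = t_num, kind = x$kind, gps = gps,
                 payload = x$payload %||% list(),
                 member_alias = x$member_alias)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alarm record: the two-minute window around a triggered alarm
#'
#' When the front-end detector raises an alarm, the IMU records spanning
#' two minutes around the trigger (whether the alarm turns out true or
#' false) are submitted to the server. A caregiver later annotates the
#' record TRUE_ALARM or FALSE_ALARM; annotated records feed
#' [build_training_set()] and [derive_thresholds()].
#'
#' @param member_id membership identification string.
#' @param trigger_t trigger time in seconds (series timebase).
#' @param imu_window [imu_series()] of at most 120 s around the trigger.
#' @param gps optional `c(lat, lon)` at the trigger.
#' @param fall_class optional known fall type of a true alarm.
#' @param truncated whether the window was clipped at a series boundary.
#' @return an `alarm_record` list with `annotation = "UNREVIEWED"`.
#' @export
alarm_record <- function(member_id, trigger_t, imu_window, gps = NULL,
                         fall_class = NA_character_, truncated = FALSE) {
  stopifnot(inherits(imu_window, "imu_series"))
  dur <- nrow(imu_window) / imu_fs(imu_window)
  if (dur > 120 + 1e-9)
    stop("alarm record IMU window must not exceed 120 s; got ",
         round(dur, 2), " s")
  structure(list(member_id = member_id, trigger_t = trigger_t,
                 imu_window = imu_window, gps = gps,
                 fall_class = fall_class, truncated = truncated,
                 annotation = "UNREVIEWED", annotator = NA_character_),
            class = "alarm_record")
}

#' Extract the alarm window around a trigger
#'
#' Cuts `[trigger_t - span/2, trigger_t + span/2]` out of a series,
#' clipping at the series bounds (the record is flagged `truncated` when
#' clipped). Sample spacing is preserved.
#'
#' @param series an [imu_series()].
#' @param trigger_t trigger time, must lie within the series time range.
#' @param span total window span in seconds (default the two-minute rule).
#' @param member_id membership identification for the record.
#' @param gps optional trigger-time GPS point.
#' @return an [alarm_record()].
#' @export
extract_alarm_window <- function(series, trigger_t, span = 120,
                                 member_id = "member", gps = NULL) {
  stopifnot(inherits(series, "imu_series"))
  tvec <- series$t
  if (trigger_t < tvec[1L] || trigger_t > tvec[length(tvec)])
    stop("trigger_t lies outside the series time range")
  lo <- trigger_t - span / 2
  hi <- trigger_t + span / 2
  # half-open [lo, hi): a fully interior window has exactly span * fs samples
  keep <- which(tvec >= lo - 1e-9 & tvec < hi - 1e-9)
  truncated <- lo < tvec[1L] - 1e-9 || hi > tvec[length(tvec)] + 1e-9
  win <- as.data.frame(series)[keep, ]
  alarm_record(member_id, trigger_t,
               new_imu_series(win, imu_fs(series)), gps = gps,
               truncated = truncated)
}

#' Annotate an alarm record as a true or false alarm
#'
#' Caregiver (or relative) confirmation step. Re-annotating an already
#' reviewed record requires `override = TRUE`. The IMU window is never
#' touched.
#'
#' @param record an [alarm_record()].
#' @param label `"TRUE_ALARM"` or `"FALSE_ALARM"`.
#' @param annotator annotator identifier string.
#' @param override allow re-annotation of a reviewed record.
#' @param fall_class optionally record the fall type of a true alarm.
#' @return the annotated [alarm_record()].
#' @export
annotate_alarm <- function(record, label, annotator, override = FALSE,
                           fall_class = NULL) {
  stopifnot(inherits(record, "alarm_record"))
  if (!label %in% c("TRUE_ALARM", "FALSE_ALARM"))
    stop("label must be TRUE_ALARM or FALSE_ALARM")
  if (record$annotation != "UNREVIEWED" && !override)
    stop("record already annotated (", record$annotation,
         "); pass override = TRUE to re-annotate")
  record$annotation <- label
  record$annotator <- annotator
  if (!is.null(fall_class)) record$fall_class <- fall_class
  record
}

#' Build a classifier/threshold training set from annotated alarm records
#'
#' Every record must be annotated. Each record's IMU window is cut into
#' fixed-width sliding windows; windows of TRUE_ALARM records are labelled
#' with the record's fall class when known, windows of FALSE_ALARM records
#' are labelled `"NON_FALL"` (negatives for threshold derivation; filter
#' them out before [train_classifier()], which takes fall classes only).
#'
#' @param records list of annotated [alarm_record()] objects.
#' @param config a [window_config()].
#' @return a list with `windows` (all labelled [feature_window()]s) and
#'   `labels`.
#' @export
build_training_set <- function(records, config = window_config()) {
  unrev <- vapply(records, function(r) r$annotation == "UNREVIEWED",
                  logical(1L))
  if (any(unrev))
    stop("unreviewed alarm records for member(s): ",
         paste(unique(vapply(records[unrev], function(r) r$member_id,
                             character(1L))), collapse = ", "))
  windows <- list()
  for (r in records) {
    lab <- if (r$annotation == "TRUE_ALARM") {
      if (!is.na(r$fall_class)) r$fall_class else NA_character_
    } else "NON_FALL"
    ws <- sliding_windows(r$imu_window, config)
    for (w in ws) {
      w$label <- lab
      windows[[length(windows) + 1L]] <- w
    }
  }
  list(windows = windows,
       labels = vapply(windows, function(w) w$label, character(1L)))
}
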