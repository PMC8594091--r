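#' WGS84 GPS track
#'
#' A data frame with columns `t` (epoch seconds, non-decreasing), `lat`,
#' `lon` (WGS84 decimal degrees), tagged with a wearer identifier.
#'
#' @param df data frame with columns `t, lat, lon`.
#' @param wearer_id wearer identifier string.
#' @return an object of class `geo_track` (a data frame).
#' @export
geo_track <- function(df, wearer_id = "wearer") {
  if (!is.data.frame(df) || !all(c("t", "lat", "lon") %in% names(df)))
    stop("geo_track requires columns t, lat, lon")
  df <- as.data.frame(df)[c("t", "lat", "lon")]
  if (nrow(df) == 0L) stop("geo_track must contain at least one point")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("coordinates out of WGS84 range")
  if (is.unsorted(df$t)) stop("timestamps must be non-decreasing")
  structure(df, wearer_id = wearer_id, class = c("geo_track", "data.frame"))
}

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Symmetric, zero for
#' identical coordinates. Vectorised over rows.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees.
#' @return distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of WGS84 range")
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = EARTH_RADIUS_M))
}

#' Electronic fence (geofence)
#'
#' Either a circle (`center = c(lat, lon)` with `radius_m`) or a polygon
#' (closed, non-self-intersecting vertex ring given as a data frame or
#' matrix of `lat`, `lon`). The boundary is closed: a point exactly on the
#' boundary counts as inside. At most one fence should carry
#' `is_home = TRUE`; it drives HOME/AWAY events.
#'
#' @param id fence identifier string.
#' @param center `c(lat, lon)` for a circle fence.
#' @param radius_m circle radius in metres (> 0).
#' @param ring two-column (`lat`, `lon`) matrix/data frame of polygon
#'   vertices for a polygon fence; an unclosed ring is closed automatically.
#' @param is_home whether this fence is the wearer's home.
#' @return a `geofence` list with `kind` `"circle"` or `"polygon"`.
#' @export
geofence <- function(id, center = NULL, radius_m = NULL, ring = NULL,
                     is_home = FALSE) {
  if (!is.null(ring)) {
    ring <- as.matrix(as.data.frame(ring)[c("lat", "lon")])
    if (nrow(ring) < 3L) stop("polygon ring needs at least 3 vertices")
    if (any(ring[1L, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
    structure(list(id = id, kind = "polygon", ring = ring, is_home = is_home),
              class = "geofence")
  } else {
    if (is.null(center) || is.null(radius_m))
      stop("a circle fence needs center and radius_m")
    if (radius_m <= 0) stop("radius_m must be positive")
    structure(list(id = id, kind = "circle",
                   center = c(lat = center[[1L]], lon = center[[2L]]),
                   radius_m = radius_m, is_home = is_home),
              class = "geofence")
  }
}

# even-odd ray casting in lon/lat plane; boundary points count as inside
point_in_ring <- function(lat, lon, ring) {
  rl <- ring[, "lat"]; rn <- ring[, "lon"]
  n <- length(rl)
  out <- logical(length(lat))
  for (p in seq_along(lat)) {
    x <- lon[p]; y <- lat[p]
    inside <- FALSE; on_edge <- FALSE
    for (i in seq_len(n - 1L)) {
      x1 <- rn[i]; y1 <- rl[i]; x2 <- rn[i + 1L]; y2 <- rl[i + 1L]
      # on-segment check
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE; break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
        if (x < xint) inside <- !inside
      }
    }
    out[p] <- on_edge || inside
  }
  out
}

#' Test whether points fall inside a fence
#'
#' Closed-boundary convention: a point exactly on the circle or ring
#' boundary is inside.
#'
#' @param fence a [geofence()].
#' @param lat,lon coordinate vectors.
#' @return logical vector.
#' @export
in_fence <- function(fence, lat, lon) {
  stopifnot(inherits(fence, "geofence"))
  if (fence$kind == "circle") {
    # nanometre slack keeps the closed-boundary convention stable under
    # floating-point rounding of the great-circle distance
    haversine_m(lat, lon, fence$center[["lat"]], fence$center[["lon"]]) <=
      fence$radius_m + 1e-9
  } else {
    point_in_ring(lat, lon, fence$ring)
  }
}

location_event <- function(kind, t_start, t_end, fence_id = NA_character_,
                           centroid_lat = NA_real_, centroid_lon = NA_real_) {
  data.frame(kind = kind, fence_id = fence_id, t_start = t_start,
             t_end = t_end, centroid_lat = centroid_lat,
             centroid_lon = centroid_lon, stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(kind = character(), fence_id = character(), t_start = numeric(),
             t_end = numeric(), centroid_lat = numeric(),
             centroid_lon = numeric(), stringsAsFactors = FALSE)
}

#' Detect fence enter/exit and home/away events on a track
#'
#' Emits one ENTER per outside-to-inside transition and one EXIT per
#' inside-to-outside transition, per fence; the initial state is taken from
#' the first point (no spurious event at track start). For the fence with
#' `is_home = TRUE`, HOME and AWAY events accompany ENTER and EXIT. Events
#' are returned in time order.
#'
#' @param track a [geo_track()].
#' @param fences list of [geofence()] objects (empty list gives no events).
#' @return data frame of events with columns
#'   `kind, fence_id, t_start, t_end, centroid_lat, centroid_lon`.
#' @export
detect_fence_events <- function(track, fences) {
  stopifnot(inherits(track, "geo_track"))
  events <- list()
  for (f in fences) {
    inside <- in_fence(f, track$lat, track$lon)
    if (length(inside) < 2L) next
    trans <- which(inside[-1L] != inside[-length(inside)]) + 1L
    for (i in trans) {
      kind <- if (inside[i]) "ENTER" else "EXIT"
      events[[length(events) + 1L]] <-
        location_event(kind, track$t[i], track$t[i], f$id)
      if (isTRUE(f$is_home)) {
        events[[length(events) + 1L]] <-
          location_event(if (inside[i]) "HOME" else "AWAY",
                         track$t[i], track$t[i], f$id)
      }
    }
  }
  if (length(events) == 0L) return(empty_events())
  ev <- do.call(rbind, events)
  ev[order(ev$t_start, match(ev$kind, c("ENTER", "HOME", "EXIT", "AWAY"))), ,
     drop = FALSE]
}

#' Detect loitering (halting) intervals on a track
#'
#' A LOITER event is a maximal time interval of at least `dwell_s` seconds
#' during which every point lies within `radius_m` metres of the interval's
#' first point. Events are non-overlapping; the event centroid is the mean
#' coordinate of the interval. Scanning is anchored at the first point of
#' each candidate interval, so the result is invariant to translating the
#' whole track.
#'
#' @param track a [geo_track()].
#' @param radius_m dwell radius in metres (> 0).
#' @param dwell_s minimum dwell time in seconds (> 0).
#' @return data frame of LOITER events (see [detect_fence_events()] for
#'   columns).
#' @export
detect_loitering <- function(track, radius_m = 20, dwell_s = 300) {
  stopifnot(inherits(track, "geo_track"))
  if (radius_m <= 0 || dwell_s <= 0) stop("radius_m and dwell_s must be positive")
  n <- nrow(track)
  events <- list()
  i <- 1L
  while (i <= n) {
    d <- haversine_m(track$lat[i:n], track$lon[i:n],
                     track$lat[i], track$lon[i])
    out <- which(d > radius_m)
    j <- if (length(out)) i + out[1L] - 2L else n
    if (track$t[j] - track$t[i] >= dwell_s) {
      events[[length(events) + 1L]] <- location_event(
        "LOITER", track$t[i], track$t[j],
        centroid_lat = mean(track$lat[i:j]),
        centroid_lon = mean(track$lon[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(events) == 0L) return(empty_events())
  do.call(rbind, events)
}

#' Summarise a track: distance, steps, pace, calories
#'
#' Distance is the sum of consecutive haversine distances. When an IMU
#' series is supplied, steps are counted as SVM peaks above 1.1 g separated
#' by at least 0.3 s (a conventional pedometer heuristic); calories are a
#' cosmetic fixed 0.04 kcal per step. Mean pace is distance over elapsed
#' time.
#'
#' @param track a [geo_track()].
#' @param imu optional [imu_series()] recorded alongside the track.
#' @param step_threshold_g peak threshold for step counting, g.
#' @param step_refractory_s minimum separation between counted steps, s.
#' @return list with `distance_m`, `steps`, `mean_pace_ms`, `calories_kcal`,
#'   `duration_s`.
#' @export
track_summary <- function(track, imu = NULL, step_threshold_g = 1.1,
                          step_refractory_s = 0.3) {
  stopifnot(inherits(track, "geo_track"))
  n <- nrow(track)
  dist <- if (n < 2L) 0 else
    sum(haversine_m(track$lat[-n], track$lon[-n], track$lat[-1L],
                    track$lon[-1L]))
  dur <- track$t[n] - track$t[1L]
  steps <- if (is.null(imu)) 0L else
    count_steps(imu, step_threshold_g, step_refractory_s)
  list(distance_m = dist, steps = steps,
       mean_pace_ms = if (dur > 0) dist / dur else 0,
       calories_kcal = steps * 0.04, duration_s = dur)
}

# SVM local maxima above threshold with a refractory period
count_steps <- function(imu, threshold_g = 1.1, refractory_s = 0.3) {
  stopifnot(inherits(imu, "imu_series"))
  v <- svm_g(imu)
  n <- length(v)
  if (n < 3L) return(0L)
  peak <- which(v[-c(1L, n)] >= v[-c(n - 1L, n)] &
                v[-c(1L, n)] >= v[-(1:2)] &
                v[-c(1L, n)] > threshold_g) + 1L
  if (length(peak) == 0L) return(0L)
  tt <- imu$t[peak]
  keep <- 1L
  last <- tt[1L]
  for (i in seq_along(tt)[-1L]) {
    if (tt[i] - last >= refractory_s) { keep <- c(keep, i); last <- tt[i] }
  }
  length(keep)
}

#' Read and write geofences as GeoJSON
#'
#' A FeatureCollection in which circle fences are Point features carrying a
#' `radius_m` property and polygon fences are Polygon features; both carry
#' `id` and `is_home` properties. GeoJSON coordinates are `[lon, lat]`.
#'
#' @param fences list of [geofence()] objects.
#' @param path file path.
#' @return `read_fences_geojson` returns a list of [geofence()].
#' @export
write_fences_geojson <- function(fences, path) {
  features <- lapply(fences, function(f) {
    props <- list(id = f$id, is_home = isTRUE(f$is_home))
    if (f$kind == "circle") {
      props$radius_m <- f$radius_m
      geom <- list(type = "Point",
                   coordinates = c(f$center[["lon"]], f$center[["lat"]]))
    } else {
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(f$ring)), function(i)
                     c(f$ring[i, "lon"], f$ring[i, "lat"]))))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fences_geojson
#' @export
read_fences_geojson <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  lapply(x$features, function(ft) {
    p <- ft$properties; g <- ft$geometry
    if (identical(g$type, "Point")) {
      geofence(p$id, center = c(g$coordinates[[2L]], g$coordinates[[1L]]),
               radius_m = p$radius_m, is_home = isTRUE(p$is_home))
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1L]], function(v)
        c(lat = v[[2L]], lon = v[[1L]])))
      geofence(p$id, ring = as.data.frame(ring), is_home = isTRUE(p$is_home))
    } else stop("unsupported geometry type: ", g$type)
  })
}

#' Write location events as JSON lines
#'
#' One event object per line with the fields of the event data frame.
#'
#' @param events event data frame from [detect_fence_events()] or
#'   [detect_loitering()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    row <- as.list(events[i, ])
    row <- row[!vapply(row, function(v) is.na(v), logical(1L))]
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read and write the track CSV interchange format
#'
#' Header `t,lat,lon`; `t` epoch seconds, coordinates WGS84 decimal degrees.
#'
#' @param track a [geo_track()].
#' @param path file path.
#' @param wearer_id wearer identifier for the returned track.
#' @return `read_track_csv` returns a [geo_track()].
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "geo_track"))
  write.csv(as.data.frame(track), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path, wearer_id = "wearer") {
  geo_track(read.csv(path), wearer_id = wearer_id)
}
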