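# Ping ingestion, trip segmentation, fishing-point detection and fishing
# hours. All downstream maps and effort series build on these operations.

#' Gear-specific fishing speed bands
#'
#' Speed-over-ground intervals (knots) within which a ping is considered a
#' fishing point for each gear: towing speeds for the trawls, near-drift
#' speeds for purse seines, and a permissive catch-all for `OTHER`. These
#' are configurable working defaults, not measured constants.
#'
#' @param ... Named length-2 numeric vectors overriding individual bands,
#'   e.g. `OTB = c(2.5, 4)`.
#' @return Named list of `c(lower, upper)` per gear.
#' @export
gear_speed_bands <- function(...) {
  bands <- list(OTB = c(2.0, 4.5), TBB = c(4.0, 7.0), PTM = c(2.0, 5.0),
                PS = c(0.0, 1.5), OTHER = c(0.0, 15.0))
  over <- list(...)
  for (g in names(over)) {
    check_gear(g)
    b <- as.numeric(over[[g]])
    if (length(b) != 2L || b[1] < 0 || b[1] >= b[2]) {
      stop("band for ", g, " must be c(lower, upper) with 0 <= lower < upper",
           call. = FALSE)
    }
    bands[[g]] <- b
  }
  bands
}

#' Read an AIS ping table from CSV
#'
#' Expects columns `vessel_id`, `timestamp` (ISO-8601 UTC), `lat`, `lon`,
#' `sog_knots`, `cog_degrees`. Rows violating basic invariants
#' (unparseable timestamp, |lat| > 90, lon outside \[-180, 180), negative
#' speed) are dropped with a warning reporting the count; the result is
#' sorted by vessel and time.
#'
#' @param path CSV path.
#' @return Ping table `data.frame`; the number of dropped rows is attached
#'   as attribute `n_dropped`.
#' @export
read_pings <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "timestamp", "lat", "lon", "sog_knots",
            "cog_degrees")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ping CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    df$timestamp <- as.POSIXct(character(0), tz = "UTC")
    attr(df, "n_dropped") <- 0L
    return(df)
  }
  ts <- parse_timestamps(df$timestamp)
  bad <- is.na(ts) |
    !is.finite(df$lat) | abs(df$lat) > 90 |
    !is.finite(df$lon) | df$lon < -180 | df$lon >= 180 |
    !is.finite(df$sog_knots) | df$sog_knots < 0
  if (any(bad)) {
    warning(sum(bad), " invalid ping row(s) dropped", call. = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  df$timestamp <- ts[!bad]
  df <- df[order(df$vessel_id, df$timestamp), ]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- sum(bad)
  df
}

#' Cut ping streams into trips
#'
#' A vessel's pings are split wherever the gap between consecutive reports
#' exceeds `max_gap_hours`; within a trip every inter-ping gap is at most
#' the threshold, and the trips of a vessel partition its pings. Applying
#' the segmentation to already-segmented trips is a no-op.
#'
#' @param pings Ping table (sorted or not; it is sorted internally), or a
#'   list of trips to re-segment.
#' @param max_gap_hours Gap threshold in hours; default 4.
#' @return List of trips; each trip is a `data.frame` of pings with
#'   attributes `vessel_id`, `start`, `end`.
#' @export
segment_trips <- function(pings, max_gap_hours = 4) {
  stopifnot(max_gap_hours > 0)
  if (is.list(pings) && !is.data.frame(pings)) {
    pings <- do.call(rbind, pings)
  }
  pings <- pings[order(pings$vessel_id, pings$timestamp), , drop = FALSE]
  out <- list()
  for (v in unique(pings$vessel_id)) {
    p <- pings[pings$vessel_id == v, , drop = FALSE]
    gaps <- diff(as.numeric(p$timestamp)) / 3600
    trip_id <- cumsum(c(0, gaps > max_gap_hours))
    for (k in unique(trip_id)) {
      tp <- p[trip_id == k, , drop = FALSE]
      rownames(tp) <- NULL
      attr(tp, "vessel_id") <- v
      attr(tp, "start") <- tp$timestamp[1L]
      attr(tp, "end") <- tp$timestamp[nrow(tp)]
      out[[length(out) + 1L]] <- tp
    }
  }
  out
}

# Lenient ISO-8601 timestamp parsing: rows that match none of the accepted
# formats come back NA (and are then dropped with a warning upstream).
parse_timestamps <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS")
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in fmts) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

# Great-circle distance (km) from each row of (lon, lat) to a point.
dist_to_point_km <- function(lon, lat, point) {
  geosphere::distHaversine(cbind(lon, lat), point) / 1000
}

#' Flag fishing points within a trip
#'
#' A ping is flagged as fishing when its speed-over-ground lies inside the
#' gear's speed band. For purse seines (`PS`), whose fishing band includes
#' near-zero speeds, pings within `port_buffer_km` of either trip endpoint
#' are excluded so that port dwell is not mistaken for setting.
#'
#' @param trip A trip from [segment_trips()] (a ping `data.frame`).
#' @param gear Gear label of the vessel.
#' @param bands Speed bands from [gear_speed_bands()].
#' @param port_buffer_km Endpoint buffer used for `PS`; default 1 km.
#' @return The trip with an additional logical `fishing` column.
#' @export
detect_fishing_points <- function(trip, gear, bands = gear_speed_bands(),
                                  port_buffer_km = 1) {
  check_gear(gear)
  b <- bands[[gear]]
  flag <- trip$sog_knots >= b[1] & trip$sog_knots <= b[2]
  if (gear == "PS" && nrow(trip) > 0L) {
    n <- nrow(trip)
    d_start <- dist_to_point_km(trip$lon, trip$lat,
                                c(trip$lon[1L], trip$lat[1L]))
    d_end <- dist_to_point_km(trip$lon, trip$lat,
                              c(trip$lon[n], trip$lat[n]))
    flag <- flag & d_start > port_buffer_km & d_end > port_buffer_km
  }
  out <- trip
  out$fishing <- flag
  for (a in c("vessel_id", "start", "end")) attr(out, a) <- attr(trip, a)
  out
}

# Consecutive-fishing intervals of a flagged trip: interval i spans pings
# (i, i+1) with both flagged and gap <= cap. Returns first-ping anchors and
# interval hours; shared by fishing_hours() and grid_effort() so that the
# gridded total equals the summed trip hours exactly.
fishing_intervals <- function(trip, max_interval_hours = 1) {
  n <- nrow(trip)
  if (n < 2L || is.null(trip$fishing)) {
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      hours = numeric(0)))
  }
  dt <- diff(as.numeric(trip$timestamp)) / 3600
  both <- trip$fishing[-n] & trip$fishing[-1L] & dt <= max_interval_hours
  data.frame(lon = trip$lon[-n][both], lat = trip$lat[-n][both],
             timestamp = trip$timestamp[-n][both], hours = dt[both])
}

#' Fishing hours of a flagged trip
#'
#' Sums the time between consecutive pings that are both flagged as fishing
#' and at most `max_interval_hours` apart, so reporting dropouts do not
#' inflate the total.
#'
#' @param trip A flagged trip from [detect_fishing_points()].
#' @param max_interval_hours Per-interval cap in hours; default 1.
#' @return Non-negative hours.
#' @export
fishing_hours <- function(trip, max_interval_hours = 1) {
  sum(fishing_intervals(trip, max_interval_hours)$hours)
}

#' Displacement-derived speed of a trip
#'
#' Validation utility: speeds recomputed from consecutive positions and
#' time gaps (knots). The analysis pipeline always uses the reported
#' speed-over-ground; this is only for checking consistency of a track.
#'
#' @param trip A trip `data.frame`.
#' @return Numeric vector of length `nrow(trip) - 1`.
#' @export
speed_from_displacement <- function(trip) {
  n <- nrow(trip)
  if (n < 2L) return(numeric(0))
  d_km <- geosphere::distHaversine(cbind(trip$lon[-n], trip$lat[-n]),
                                   cbind(trip$lon[-1L], trip$lat[-1L])) / 1000
  dt_h <- diff(as.numeric(trip$timestamp)) / 3600
  d_km / dt_h / KNOT_KMH
}
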