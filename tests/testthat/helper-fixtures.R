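# Programmatic fixtures shared across test files.

# A minimal trip data.frame at fixed cadence. Positions advance eastward
# consistently with the given speeds unless static = TRUE.
make_trip <- function(speeds, interval_min = 5, vessel_id = "V1",
                      lon0 = 13.5, lat0 = 43.5, static = FALSE,
                      t0 = as.POSIXct("2020-03-01 06:00:00", tz = "UTC")) {
  n <- length(speeds)
  ts <- t0 + (seq_len(n) - 1) * interval_min * 60
  lon <- rep(lon0, n)
  if (!static && n > 1) {
    step_deg <- speeds[-n] * 1.852 * (interval_min / 60) /
      (111.320 * cos(lat0 * pi / 180))
    lon <- lon0 + c(0, cumsum(step_deg))
  }
  tp <- data.frame(vessel_id = vessel_id, timestamp = ts, lat = lat0,
                   lon = lon, sog_knots = speeds,
                   cog_degrees = 90, stringsAsFactors = FALSE)
  attr(tp, "vessel_id") <- vessel_id
  tp
}

# Write a ping CSV with the standard dialect and return its path.
write_ping_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent, loop-based Schaefer viability oracle used to cross-check
# the vectorised sampler screen.
oracle_viable <- function(a, r, kq) {
  if (max(a) > kq) return(FALSE)
  for (t in seq_len(length(a) - 1)) {
    cq <- a[t] + r * a[t] * (1 - a[t] / kq) - a[t + 1]
    if (cq < 0) return(FALSE)
  }
  TRUE
}
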