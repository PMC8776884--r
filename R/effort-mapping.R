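# Gridded fishing effort: half-open lat-lon cells on an integer-degree
# lattice, log-normal low/medium/high classification, period comparison
# and effort-weighted barycentres.

# Snap coordinates to their cell's lower-left corner. Cells are half-open
# [lon_min, lon_min + res) x [lat_min, lat_min + res), anchored at integer
# degrees. Rounding guards against 13.1 / 0.1 style floating artefacts.
cell_floor <- function(x, res) {
  round(floor(round(x / res, 9)) * res, 9)
}

new_effort_grid <- function(df, resolution, period = NULL, gear = "ALL") {
  rownames(df) <- NULL
  structure(df, class = c("effort_grid", "data.frame"),
            resolution = resolution, period = period, gear = gear)
}

#' Grid fishing hours onto lat-lon cells
#'
#' Accumulates the fishing hours of flagged trips into regular half-open
#' cells of the given resolution; each consecutive-fishing interval is
#' assigned to the cell of its first ping. The gridded total equals the sum
#' of [fishing_hours()] over the trips (conservation) because both are
#' built from the same intervals.
#'
#' @param trips List of flagged trips (from [detect_fishing_points()]), or
#'   a single flagged trip.
#' @param resolution Cell size in degrees (> 0); 0.1 for the fine AIS
#'   analysis, 0.5 for coarse products.
#' @param period Optional `c(year, month)` (or just year) filter on the
#'   interval start time; also recorded on the grid.
#' @param gear Optional gear label: trips of other gears are skipped.
#'   Requires `gear_map`.
#' @param gear_map Named character vector vessel_id -> gear.
#' @param max_interval_hours Per-interval cap, as in [fishing_hours()].
#' @return An `"effort_grid"`: a `data.frame` with `lon_min`, `lat_min`,
#'   `hours` and attributes `resolution`, `period`, `gear`.
#' @export
grid_effort <- function(trips, resolution, period = NULL, gear = NULL,
                        gear_map = NULL, max_interval_hours = 1) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (is.data.frame(trips)) trips <- list(trips)
  acc <- list()
  for (trip in trips) {
    if (!is.null(gear)) {
      vid <- attr(trip, "vessel_id") %||% trip$vessel_id[1]
      if (is.null(gear_map) || !identical(unname(gear_map[vid]), gear)) next
    }
    iv <- fishing_intervals(trip, max_interval_hours)
    if (nrow(iv) == 0L) next
    if (!is.null(period)) {
      lt <- as.POSIXlt(iv$timestamp, tz = "UTC")
      keep <- (lt$year + 1900L) == period[1]
      if (length(period) > 1L) keep <- keep & (lt$mon + 1L) == period[2]
      iv <- iv[keep, , drop = FALSE]
      if (nrow(iv) == 0L) next
    }
    acc[[length(acc) + 1L]] <- iv
  }
  if (length(acc) == 0L) {
    g <- data.frame(lon_min = numeric(0), lat_min = numeric(0),
                    hours = numeric(0))
    return(new_effort_grid(g, resolution, period, gear %||% "ALL"))
  }
  iv <- do.call(rbind, acc)
  lon_min <- cell_floor(iv$lon, resolution)
  lat_min <- cell_floor(iv$lat, resolution)
  key <- paste(lon_min, lat_min)
  hours <- tapply(iv$hours, key, sum)
  first <- !duplicated(key)
  g <- data.frame(lon_min = lon_min[first], lat_min = lat_min[first])
  g$hours <- as.numeric(hours[paste(g$lon_min, g$lat_min)])
  g <- g[order(g$lon_min, g$lat_min), ]
  new_effort_grid(g, resolution, period, gear %||% "ALL")
}

#' Build an effort grid directly from cell values
#'
#' Convenience constructor for tests and external data products: cell
#' corners are snapped to the lattice.
#'
#' @param lon_min,lat_min Cell lower-left corners.
#' @param hours Non-negative hours per cell.
#' @param resolution Cell size in degrees.
#' @param period,gear Recorded on the grid.
#' @return An `"effort_grid"`.
#' @export
effort_grid <- function(lon_min, lat_min, hours, resolution,
                        period = NULL, gear = "ALL") {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  if (any(hours < 0)) stop("hours must be non-negative", call. = FALSE)
  g <- data.frame(lon_min = cell_floor(lon_min, resolution),
                  lat_min = cell_floor(lat_min, resolution),
                  hours = as.numeric(hours))
  new_effort_grid(g, resolution, period, gear)
}

#' Classify grid cells as low/medium/high under a log-normal model
#'
#' Positive cells are assumed log-normally distributed: with `mu` and
#' `sigma` the mean and sample standard deviation of `log10(value)` over
#' the positive cells of the reference grid (default: the grid itself), a
#' cell is `HIGH` when `log10(value) >= mu + sigma`, `LOW` when
#' `log10(value) < mu - sigma`, and `MEDIUM` otherwise. When `sigma` is 0
#' every cell is `MEDIUM`. The quantile variant cuts at the probability
#' levels a one-sigma rule would give under exact log-normality
#' (15.87% / 84.13%).
#'
#' @param grid An `"effort_grid"` (or any data.frame with a `hours` or
#'   `count` value column).
#' @param reference Optional grid supplying the classification thresholds,
#'   e.g. a baseline year used for all later years.
#' @param method `"sigma"` (default) or `"quantile"`.
#' @return `grid` with an added `class` column (positive cells only;
#'   zero-valued cells get `NA`), thresholds attached as attribute
#'   `thresholds`.
#' @export
classify_cells_lognormal <- function(grid, reference = NULL,
                                     method = c("sigma", "quantile")) {
  method <- match.arg(method)
  value_col <- if ("hours" %in% names(grid)) "hours" else "count"
  ref <- reference %||% grid
  ref_col <- if ("hours" %in% names(ref)) "hours" else "count"
  rv <- ref[[ref_col]][ref[[ref_col]] > 0]
  if (length(rv) == 0L) {
    stop("reference grid has no positive cells", call. = FALSE)
  }
  lx <- log10(rv)
  if (method == "sigma") {
    mu <- mean(lx)
    sigma <- if (length(lx) > 1L) stats::sd(lx) else 0
    lo <- mu - sigma
    hi <- mu + sigma
  } else {
    qs <- stats::quantile(lx, c(stats::pnorm(-1), stats::pnorm(1)))
    lo <- qs[[1]]
    hi <- qs[[2]]
    sigma <- hi - lo
  }
  v <- grid[[value_col]]
  cls <- rep(NA_character_, nrow(grid))
  pos <- v > 0
  lg <- log10(v[pos])
  cls[pos] <- if (sigma == 0) "MEDIUM" else
    ifelse(lg >= hi, "HIGH", ifelse(lg < lo, "LOW", "MEDIUM"))
  out <- grid
  out$class <- cls
  for (a in c("resolution", "period", "gear")) {
    attr(out, a) <- attr(grid, a)
  }
  class(out) <- class(grid)
  attr(out, "thresholds") <- c(lo = lo, hi = hi)
  out
}

# Shared lattice check for cell-wise grid operations.
check_same_lattice <- function(a, b) {
  ra <- attr(a, "resolution"); rb <- attr(b, "resolution")
  if (is.null(ra) || is.null(rb) || !isTRUE(all.equal(ra, rb))) {
    stop("grids are on different lattices (resolution mismatch)",
         call. = FALSE)
  }
  ra
}

#' Compare two effort grids
#'
#' Summarises the change between two periods on the same lattice: totals,
#' absolute and percent change, active-cell counts, per-cell differences
#' and the overlap of HIGH-classified cells (when both grids carry
#' classes).
#'
#' @param grid_a,grid_b Two `"effort_grid"`s with equal resolution.
#' @return A list with `total_a`, `total_b`, `diff_hours`, `pct_change`,
#'   `cells_a`, `cells_b`, `cell_diff` (data.frame of per-cell changes) and
#'   `high_overlap` (count of cells HIGH in both, or `NA` without classes).
#' @export
compare_periods <- function(grid_a, grid_b) {
  check_same_lattice(grid_a, grid_b)
  pos_a <- grid_a[grid_a$hours > 0, , drop = FALSE]
  pos_b <- grid_b[grid_b$hours > 0, , drop = FALSE]
  total_a <- sum(grid_a$hours)
  total_b <- sum(grid_b$hours)
  key_a <- paste(pos_a$lon_min, pos_a$lat_min)
  key_b <- paste(pos_b$lon_min, pos_b$lat_min)
  keys <- union(key_a, key_b)
  ha <- stats::setNames(pos_a$hours, key_a)[keys]
  hb <- stats::setNames(pos_b$hours, key_b)[keys]
  ha[is.na(ha)] <- 0; hb[is.na(hb)] <- 0
  cd <- do.call(rbind, strsplit(keys, " "))
  cell_diff <- data.frame(lon_min = as.numeric(cd[, 1]),
                          lat_min = as.numeric(cd[, 2]),
                          hours_a = as.numeric(ha), hours_b = as.numeric(hb),
                          diff = as.numeric(hb - ha))
  high_overlap <- NA_integer_
  if (!is.null(grid_a$class) && !is.null(grid_b$class)) {
    high_a <- key_a[pos_a$class %in% "HIGH"]
    high_b <- key_b[pos_b$class %in% "HIGH"]
    high_overlap <- length(intersect(high_a, high_b))
  }
  list(total_a = total_a, total_b = total_b,
       diff_hours = total_b - total_a,
       pct_change = if (total_a > 0) 100 * (total_b - total_a) / total_a
                    else NA_real_,
       cells_a = nrow(pos_a), cells_b = nrow(pos_b),
       cell_diff = cell_diff, high_overlap = high_overlap)
}

#' Effort-weighted barycentre of a grid
#'
#' The hours-weighted mean position of the active cell centres: the
#' monthly "centre of gravity" of a fleet's fishing activity.
#'
#' @param grid An `"effort_grid"` with at least one positive cell.
#' @return One-row `data.frame`: `gear`, `year`, `month` (NA when the grid
#'   is not monthly), `lon`, `lat`, `total_hours`.
#' @export
monthly_barycentre <- function(grid) {
  pos <- grid[grid$hours > 0, , drop = FALSE]
  if (nrow(pos) == 0L) stop("grid has no positive cells", call. = FALSE)
  res <- attr(grid, "resolution")
  w <- pos$hours / sum(pos$hours)
  period <- attr(grid, "period")
  data.frame(gear = attr(grid, "gear") %||% "ALL",
             year = if (length(period) >= 1L) period[1] else NA_integer_,
             month = if (length(period) >= 2L) period[2] else NA_integer_,
             lon = sum(w * (pos$lon_min + res / 2)),
             lat = sum(w * (pos$lat_min + res / 2)),
             total_hours = sum(pos$hours))
}

#' Extent of a barycentre series
#'
#' Bounding box of monthly barycentre positions and the latitudinal range,
#' the scalar used to compare the roaming extent of different fleets.
#'
#' @param series `data.frame` of barycentre points (rows of
#'   [monthly_barycentre()]).
#' @return List with `bbox` (`lon_min`, `lon_max`, `lat_min`, `lat_max`)
#'   and `lat_range` in degrees.
#' @export
barycentre_extent <- function(series) {
  if (is.null(nrow(series)) || nrow(series) == 0L) {
    stop("empty barycentre series", call. = FALSE)
  }
  bbox <- c(lon_min = min(series$lon), lon_max = max(series$lon),
            lat_min = min(series$lat), lat_max = max(series$lat))
  list(bbox = bbox, lat_range = unname(bbox["lat_max"] - bbox["lat_min"]))
}

#' Write an effort or species grid to CSV
#'
#' @param grid Grid `data.frame` (effort or species richness).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  out <- as.data.frame(grid)
  out$resolution_deg <- attr(grid, "resolution")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
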