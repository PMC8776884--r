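# Overlap of fishing effort with endangered, threatened and protected
# (ETP) species: richness grids from range polygons, impact cells, and
# effort-at-risk series.

new_species_grid <- function(df, resolution) {
  rownames(df) <- NULL
  structure(df, class = c("species_grid", "data.frame"),
            resolution = resolution)
}

# Full lattice of cell corners covering a bbox c(lon_min, lat_min,
# lon_max, lat_max) at the given resolution.
lattice_cells <- function(bbox, resolution) {
  lon <- seq(cell_floor(bbox[1], resolution),
             cell_floor(bbox[3] - 1e-9, resolution), by = resolution)
  lat <- seq(cell_floor(bbox[2], resolution),
             cell_floor(bbox[4] - 1e-9, resolution), by = resolution)
  expand.grid(lon_min = round(lon, 9), lat_min = round(lat, 9))
}

#' Species-richness grid from range polygons
#'
#' Counts, for every cell of the lattice, the number of distinct species
#' whose range intersects the cell. Any overlap counts -- including mere
#' edge or corner contact (closed-set convention, conservative for impact
#' assessment) -- and each species is counted once per cell regardless of
#' how many of its range parts touch it.
#'
#' @param ranges Named list: species id -> list of polygon rings (each an
#'   n x 2 lon/lat matrix), e.g. from [read_species_ranges()].
#' @param bbox `c(lon_min, lat_min, lon_max, lat_max)` of the lattice.
#' @param resolution Cell size in degrees.
#' @return A `"species_grid"`: `data.frame` with `lon_min`, `lat_min`,
#'   `count` (every lattice cell, zeros included).
#' @export
species_richness_grid <- function(ranges, bbox, resolution) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  cells <- lattice_cells(bbox, resolution)
  cells$count <- 0L
  if (length(ranges) == 0L) {
    warning("empty range set: species counts are all zero", call. = FALSE)
    return(new_species_grid(cells, resolution))
  }
  rings_list <- lapply(ranges, function(r) lapply(r, as.matrix))
  for (i in seq_len(nrow(cells))) {
    rect <- c(cells$lon_min[i], cells$lat_min[i],
              cells$lon_min[i] + resolution, cells$lat_min[i] + resolution)
    cells$count[i] <- sum(vapply(rings_list, range_intersects_rect,
                                 logical(1), rect = rect))
  }
  new_species_grid(cells, resolution)
}

#' Cross-classify effort and species richness into impact cells
#'
#' Joins a classified effort grid with a classified richness grid on their
#' common lattice; a cell is flagged as a potential-impact location exactly
#' when both its effort and its richness class are `HIGH`.
#'
#' @param effort A classified `"effort_grid"` (see
#'   [classify_cells_lognormal()]).
#' @param richness A classified `"species_grid"`.
#' @return `data.frame` with one row per cell active in either grid:
#'   `lon_min`, `lat_min`, `effort_class`, `richness_class`, `impact`;
#'   the (effort class x richness class) contingency table is attached as
#'   attribute `summary`.
#' @export
classify_impact <- function(effort, richness) {
  check_same_lattice(effort, richness)
  if (is.null(effort$hours) || is.null(richness$count)) {
    stop("expected a classified effort grid and a classified species grid",
         call. = FALSE)
  }
  if (is.null(effort$class) || is.null(richness$class)) {
    stop("both grids must be classified first", call. = FALSE)
  }
  e <- effort[effort$hours > 0, , drop = FALSE]
  r <- richness[richness$count > 0, , drop = FALSE]
  key_e <- paste(e$lon_min, e$lat_min)
  key_r <- paste(r$lon_min, r$lat_min)
  keys <- union(key_e, key_r)
  ec <- stats::setNames(e$class, key_e)[keys]
  rc <- stats::setNames(r$class, key_r)[keys]
  cd <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(lon_min = as.numeric(cd[, 1]),
                    lat_min = as.numeric(cd[, 2]),
                    effort_class = unname(ec), richness_class = unname(rc),
                    stringsAsFactors = FALSE)
  out$impact <- !is.na(out$effort_class) & !is.na(out$richness_class) &
    out$effort_class == "HIGH" & out$richness_class == "HIGH"
  attr(out, "summary") <- table(effort = factor(out$effort_class,
                                                c("LOW", "MEDIUM", "HIGH")),
                                richness = factor(out$richness_class,
                                                  c("LOW", "MEDIUM", "HIGH")))
  out
}

#' Monthly fishing hours at impact locations
#'
#' Sums, for each monthly per-gear grid, the hours falling into a fixed
#' set of impact cells -- tracking whether effort at the locations of
#' highest potential impact recovers differently from total effort.
#'
#' @param monthly_grids List of `"effort_grid"`s (typically one per gear
#'   and month, each carrying `period` and `gear` attributes).
#' @param impact_cells `data.frame` with `lon_min`, `lat_min` of the
#'   impact cells (e.g. the flagged rows of [classify_impact()]).
#' @return `data.frame` with `gear`, `year`, `month`, `hours` (hours inside
#'   impact cells) and `total_hours` for that grid.
#' @export
effort_at_risk_series <- function(monthly_grids, impact_cells) {
  keys <- paste(impact_cells$lon_min, impact_cells$lat_min)
  rows <- lapply(monthly_grids, function(g) {
    period <- attr(g, "period")
    inside <- paste(g$lon_min, g$lat_min) %in% keys
    data.frame(gear = attr(g, "gear") %||% "ALL",
               year = if (length(period) >= 1L) period[1] else NA_integer_,
               month = if (length(period) >= 2L) period[2] else NA_integer_,
               hours = sum(g$hours[inside]),
               total_hours = sum(g$hours))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a clustered species-richness grid
#'
#' Generates a synthetic ETP richness layer: inside a circular hotspot all
#' `n_species` are present; outside, each species is present independently
#' with probability `p_background`. The per-species ranges (unions of the
#' presence cells, inset by a hair so a range only touches its own cells)
#' are attached so that the grid can be re-derived exactly from its own
#' polygons via [species_richness_grid()].
#'
#' @param bbox `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param resolution Cell size in degrees (> 0).
#' @param n_species Number of species (>= 1).
#' @param hotspot `c(lon, lat, radius_deg)`: centre (must lie inside the
#'   bbox) and radius in degrees.
#' @param p_background Presence probability outside the hotspot.
#' @param seed RNG seed.
#' @return A `"species_grid"` with attributes `ranges` (named list of
#'   per-species rings) and `hotspot`.
#' @export
simulate_etp_grid <- function(bbox, resolution, n_species,
                              hotspot, p_background = 0.3, seed = 1L) {
  stopifnot(resolution > 0, n_species >= 1L, length(hotspot) == 3L)
  if (hotspot[1] < bbox[1] || hotspot[1] > bbox[3] ||
      hotspot[2] < bbox[2] || hotspot[2] > bbox[4]) {
    stop("hotspot centre lies outside the bounding box", call. = FALSE)
  }
  cells <- lattice_cells(bbox, resolution)
  cx <- cells$lon_min + resolution / 2
  cy <- cells$lat_min + resolution / 2
  inside <- sqrt((cx - hotspot[1])^2 + (cy - hotspot[2])^2) <= hotspot[3]
  presence <- with_seed(seed, {
    vapply(seq_len(n_species), function(s) {
      inside | stats::runif(nrow(cells)) < p_background
    }, logical(nrow(cells)))
  })
  cells$count <- as.integer(rowSums(presence))
  eps <- resolution * 1e-3
  ranges <- lapply(seq_len(n_species), function(s) {
    idx <- which(presence[, s])
    lapply(idx, function(i) {
      x0 <- cells$lon_min[i] + eps; x1 <- cells$lon_min[i] + resolution - eps
      y0 <- cells$lat_min[i] + eps; y1 <- cells$lat_min[i] + resolution - eps
      cbind(lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1))
    })
  })
  names(ranges) <- sprintf("SP%03d", seq_len(n_species))
  out <- new_species_grid(cells, resolution)
  attr(out, "ranges") <- ranges
  attr(out, "hotspot") <- hotspot
  out
}
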