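# GeoJSON readers/writers for species ranges, grids and barycentre tracks.
# Geometries are plain lon/lat rings; jsonlite handles the encoding.

#' Read species range polygons from GeoJSON
#'
#' Expects a `FeatureCollection` of `Polygon` / `MultiPolygon` features,
#' each carrying a `species_id` property. Only outer rings are used (holes
#' in coarse range maps are ignored); features of the same species are
#' merged into one multi-ring range.
#'
#' @param path GeoJSON file path.
#' @return Named list: species id -> list of rings (n x 2 matrices).
#' @export
read_species_ranges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  out <- list()
  for (feat in gj$features) {
    sid <- feat$properties$species_id
    if (is.null(sid)) stop("feature without species_id property",
                           call. = FALSE)
    geom <- feat$geometry
    ring_of <- function(coords) {
      m <- do.call(rbind, lapply(coords, function(p) {
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))
      }))
      # drop the closing vertex GeoJSON repeats
      if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) {
        m <- m[-nrow(m), , drop = FALSE]
      }
      colnames(m) <- c("lon", "lat")
      m
    }
    rings <- switch(geom$type,
      Polygon = list(ring_of(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(poly) {
        ring_of(poly[[1]])
      }),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    out[[sid]] <- c(out[[sid]], rings)
  }
  out
}

# Close a ring for GeoJSON output (first vertex repeated last).
closed_coords <- function(ring) {
  ring <- as.matrix(ring)
  m <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write species ranges to GeoJSON
#'
#' One `MultiPolygon` feature per species with a `species_id` property;
#' inverse of [read_species_ranges()].
#'
#' @param ranges Named list: species id -> list of rings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_ranges <- function(ranges, path) {
  features <- lapply(names(ranges), function(sid) {
    list(type = "Feature",
         properties = list(species_id = sid),
         geometry = list(
           type = "MultiPolygon",
           coordinates = lapply(ranges[[sid]], function(ring) {
             list(closed_coords(ring))
           })))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a grid as GeoJSON cell polygons
#'
#' One square `Polygon` feature per cell, with the grid's value columns
#' (`hours` or `count`, and `class` when present) as properties.
#'
#' @param grid An `"effort_grid"` or `"species_grid"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  res <- attr(grid, "resolution")
  value_col <- if ("hours" %in% names(grid)) "hours" else "count"
  features <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- grid$lon_min[i]; y0 <- grid$lat_min[i]
    ring <- cbind(c(x0, x0 + res, x0 + res, x0),
                  c(y0, y0, y0 + res, y0 + res))
    props <- list(lon_min = x0, lat_min = y0, resolution_deg = res)
    props[[value_col]] <- grid[[value_col]][i]
    if (!is.null(grid$class)) props$class <- grid$class[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(closed_coords(ring))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write monthly barycentre tracks to GeoJSON
#'
#' One `LineString` per (gear, year) of monthly barycentre points, plus
#' one bounding-box `Polygon` per gear depicting the maximum extent of the
#' barycentre movements.
#'
#' @param points `data.frame` of barycentre rows ([monthly_barycentre()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barycentres_geojson <- function(points, path) {
  features <- list()
  for (g in unique(points$gear)) {
    pg <- points[points$gear == g, , drop = FALSE]
    for (y in unique(pg$year)) {
      py <- pg[pg$year == y, , drop = FALSE]
      py <- py[order(py$month), , drop = FALSE]
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(gear = g, year = y, kind = "barycentre_track"),
        geometry = list(
          type = "LineString",
          coordinates = lapply(seq_len(nrow(py)),
                               function(i) c(py$lon[i], py$lat[i]))))
    }
    ext <- barycentre_extent(pg)
    bb <- ext$bbox
    ring <- cbind(c(bb["lon_min"], bb["lon_max"], bb["lon_max"],
                    bb["lon_min"]),
                  c(bb["lat_min"], bb["lat_min"], bb["lat_max"],
                    bb["lat_max"]))
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      properties = list(gear = g, kind = "barycentre_extent",
                        lat_range = ext$lat_range),
      geometry = list(type = "Polygon",
                      coordinates = list(closed_coords(ring))))
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
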