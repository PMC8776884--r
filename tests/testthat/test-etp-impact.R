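# Species-richness grids, impact classification, effort at risk.

bbox <- c(13, 43, 14, 44)

test_that("cell counts equal the number of intersecting species ranges", {
  sq <- function(x0, y0, x1, y1) {
    list(cbind(lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1)))
  }
  ranges <- list(SP1 = sq(13.1, 43.1, 13.4, 43.4),
                 SP2 = sq(13.2, 43.2, 13.45, 43.45))
  g <- species_richness_grid(ranges, bbox, resolution = 0.5)
  cell <- g[g$lon_min == 13 & g$lat_min == 43, ]
  expect_equal(cell$count, 2L)

  # a range touching only a cell corner still counts (closed convention)
  corner <- list(SP1 = sq(13.5, 43.5, 13.6, 43.6))
  g2 <- species_richness_grid(corner, bbox, resolution = 0.5)
  expect_equal(g2$count[g2$lon_min == 13 & g2$lat_min == 43], 1L)
  expect_equal(g2$count[g2$lon_min == 13.5 & g2$lat_min == 43.5], 1L)
  expect_equal(g2$count[g2$lon_min == 13 & g2$lat_min == 43.5], 1L)

  # a range enclosing a whole cell (no vertex inside it) still counts
  big <- list(SP1 = sq(12.9, 42.9, 14.1, 44.1))
  g3 <- species_richness_grid(big, bbox, resolution = 0.5)
  expect_true(all(g3$count == 1L))

  expect_warning(g4 <- species_richness_grid(list(), bbox, 0.5), "empty")
  expect_true(all(g4$count == 0L))
})

test_that("adding a species range never decreases any cell count", {
  g <- simulate_etp_grid(bbox, 0.25, n_species = 4,
                         hotspot = c(13.4, 43.4, 0.3), seed = 21)
  ranges <- attr(g, "ranges")
  g_less <- species_richness_grid(ranges[1:3], bbox, 0.25)
  g_more <- species_richness_grid(ranges, bbox, 0.25)
  expect_true(all(g_more$count >= g_less$count))
})

test_that("the synthetic richness grid round-trips through its polygons", {
  g <- simulate_etp_grid(bbox, 0.25, n_species = 6,
                         hotspot = c(13.5, 43.5, 0.3), seed = 22)
  rebuilt <- species_richness_grid(attr(g, "ranges"), bbox, 0.25)
  expect_identical(g$count, rebuilt$count)

  # and through GeoJSON serialisation
  path <- tempfile(fileext = ".geojson")
  write_species_ranges(attr(g, "ranges"), path)
  back <- read_species_ranges(path)
  rebuilt2 <- species_richness_grid(back, bbox, 0.25)
  expect_identical(g$count, rebuilt2$count)
})

test_that("synthetic hotspots behave as specified", {
  # a hotspot covering the whole box with one species: every cell is 1
  g1 <- simulate_etp_grid(bbox, 0.25, n_species = 1,
                          hotspot = c(13.5, 43.5, 5), seed = 23)
  expect_true(all(g1$count == 1L))

  g10 <- simulate_etp_grid(bbox, 0.25, n_species = 10,
                           hotspot = c(13.4, 43.4, 0.2), seed = 24)
  expect_true(all(g10$count >= 0 & g10$count <= 10))
  centre <- sqrt((g10$lon_min + 0.125 - 13.4)^2 +
                   (g10$lat_min + 0.125 - 43.4)^2) <= 0.2
  expect_gt(mean(g10$count[centre]), mean(g10$count[!centre]))

  expect_identical(g10$count,
                   simulate_etp_grid(bbox, 0.25, 10, c(13.4, 43.4, 0.2),
                                     seed = 24)$count)
  expect_error(simulate_etp_grid(bbox, 0.25, 10, c(20, 50, 0.2)),
               "outside")
})

test_that("impact cells are exactly the HIGH-effort HIGH-richness cells", {
  # effort classes {10, 100, 1000} -> MEDIUM, MEDIUM, HIGH;
  # richness classes {2, 30, 900}  -> MEDIUM, MEDIUM, HIGH
  effort <- classify_cells_lognormal(
    effort_grid(c(13, 13.5, 13), c(43, 43, 43.5), c(10, 100, 1000), 0.5))
  richness <- classify_cells_lognormal(structure(
    data.frame(lon_min = c(13, 13.5, 13.5), lat_min = c(43.5, 43, 43.5),
               count = c(2, 30, 900)),
    class = c("species_grid", "data.frame"), resolution = 0.5))

  # HIGH effort sits at (13, 43.5), HIGH richness at (13.5, 43.5): disjoint
  imp <- classify_impact(effort, richness)
  expect_equal(nrow(imp), 4)  # union of active cells
  expect_equal(sum(imp$impact), 0)

  # align the HIGH effort cell with the HIGH richness cell
  effort3 <- classify_cells_lognormal(
    effort_grid(c(13, 13.5, 13.5), c(43.5, 43, 43.5),
                c(10, 100, 1000), 0.5))
  imp3 <- classify_impact(effort3, richness)
  expect_equal(sum(imp3$impact), 1)
  expect_equal(imp3$lon_min[imp3$impact], 13.5)
  expect_equal(imp3$lat_min[imp3$impact], 43.5)

  # HIGH effort with merely MEDIUM richness is not flagged
  m <- imp[imp$lon_min == 13 & imp$lat_min == 43.5, ]
  expect_equal(m$effort_class, "HIGH")
  expect_false(m$impact)
  expect_error(classify_impact(effort, effort), "classified|lattice")
})

test_that("effort at risk sums hours over impact cells only", {
  g1 <- effort_grid(c(13, 13.5), c(43, 43), c(10, 20), 0.5,
                    period = c(2020, 2), gear = "OTB")
  g2 <- effort_grid(c(13, 13.5), c(43, 43), c(5, 8), 0.5,
                    period = c(2020, 3), gear = "OTB")
  cells_none <- data.frame(lon_min = numeric(0), lat_min = numeric(0))
  s0 <- effort_at_risk_series(list(g1, g2), cells_none)
  expect_equal(s0$hours, c(0, 0))

  cells_all <- data.frame(lon_min = c(13, 13.5), lat_min = c(43, 43))
  s1 <- effort_at_risk_series(list(g1, g2), cells_all)
  expect_equal(s1$hours, s1$total_hours)
  expect_equal(s1$hours, c(30, 13))

  cells_one <- data.frame(lon_min = 13.5, lat_min = 43)
  s2 <- effort_at_risk_series(list(g1, g2), cells_one)
  expect_equal(s2$hours, c(20, 8))
  expect_true(all(s2$hours <= s2$total_hours))
  expect_equal(s2$year, c(2020, 2020))
  expect_equal(s2$month, c(2, 3))
})

test_that("a shock confined to impact cells dents that series hardest", {
  months <- 1:6
  shock <- months %in% 3:4
  grids <- lapply(months, function(m) {
    risk_hours <- if (shock[m]) 20 else 100
    effort_grid(c(13, 13.5), c(43, 43), c(200, risk_hours), 0.5,
                period = c(2020, m))
  })
  cells <- data.frame(lon_min = 13.5, lat_min = 43)
  s <- effort_at_risk_series(grids, cells)
  drop_risk <- 1 - min(s$hours) / max(s$hours)
  drop_total <- 1 - min(s$total_hours) / max(s$total_hours)
  expect_gt(drop_risk, drop_total)
  expect_equal(which.min(s$hours), 3)
})
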