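# Gridding, log-normal cell classification, period comparison, barycentres.

flag_otb <- function(trip) detect_fishing_points(trip, "OTB")

test_that("hours land in the half-open cell of the interval's first ping", {
  trip <- flag_otb(make_trip(rep(3, 13), lon0 = 13.07, lat0 = 43.04,
                             static = TRUE))
  g <- grid_effort(trip, resolution = 0.1)
  expect_equal(nrow(g), 1)
  expect_equal(g$lon_min, 13.0)
  expect_equal(g$lat_min, 43.0)
  expect_equal(g$hours, 1.0)

  # a point exactly on a cell edge belongs to the upper cell
  edge <- flag_otb(make_trip(rep(3, 13), lon0 = 13.1, lat0 = 43.0,
                             static = TRUE))
  g2 <- grid_effort(edge, resolution = 0.1)
  expect_equal(g2$lon_min, 13.1)
  expect_equal(g2$lat_min, 43.0)
  expect_error(grid_effort(trip, resolution = 0), "positive")
})

test_that("gridding conserves total fishing hours exactly", {
  fleet <- synthetic_fleet(8, seed = 12)
  pings <- simulate_ais_tracks(fleet, n_days = 2, seed = 12)
  gears <- attr(fleet, "gears")
  flagged <- lapply(segment_trips(pings), function(tp) {
    detect_fishing_points(tp, gears[[attr(tp, "vessel_id")]])
  })
  total_trips <- sum(vapply(flagged, fishing_hours, numeric(1)))
  g <- grid_effort(flagged, resolution = 0.1)
  expect_equal(sum(g$hours), total_trips, tolerance = 1e-9)
})

test_that("log-normal classes split cells at one sigma in log space", {
  g <- effort_grid(c(13.0, 13.1, 13.2), c(43, 43, 43),
                   hours = c(10, 100, 1000), resolution = 0.1)
  cls <- classify_cells_lognormal(g)
  # log10 hours are {1, 2, 3}: mu = 2, sample sd = 1, so only the top
  # cell reaches mu + sigma and none falls below mu - sigma
  expect_equal(cls$class, c("MEDIUM", "MEDIUM", "HIGH"))

  # equal cells: sigma = 0 convention, everything MEDIUM
  eq <- effort_grid(c(13.0, 13.1), c(43, 43), c(50, 50), 0.1)
  expect_equal(classify_cells_lognormal(eq)$class, c("MEDIUM", "MEDIUM"))

  empty <- effort_grid(13.0, 43, 0, 0.1)
  expect_error(classify_cells_lognormal(empty), "no positive")
})

test_that("the HIGH fraction of a log-normal field matches P(Z >= 1)", {
  set.seed(13)
  hours <- rlnorm(10000, meanlog = 3, sdlog = 1.2)
  idx <- 0:9999
  g <- effort_grid(idx %% 100 * 0.1, idx %/% 100 * 0.1,
                   hours, resolution = 0.1)
  cls <- classify_cells_lognormal(g)
  expect_lt(abs(mean(cls$class == "HIGH") - pnorm(-1)), 0.01)
  expect_lt(abs(mean(cls$class == "LOW") - pnorm(-1)), 0.01)
})

test_that("classification is monotone and honours a reference grid", {
  set.seed(14)
  g <- effort_grid(seq(13, 13.9, 0.1) |> rep(5),
                   rep(seq(43, 43.4, 0.1), each = 10),
                   rlnorm(50, 2, 1), 0.1)
  ref_cls <- classify_cells_lognormal(g)
  rank_of <- c(LOW = 1, MEDIUM = 2, HIGH = 3)
  for (i in c(3, 17, 40)) {
    bumped <- g
    bumped$hours[i] <- bumped$hours[i] * 10
    new_cls <- classify_cells_lognormal(bumped, reference = g)
    expect_gte(rank_of[new_cls$class[i]], rank_of[ref_cls$class[i]])
  }
  # the quantile variant agrees with sigma cuts on truly log-normal data
  q_cls <- classify_cells_lognormal(g, method = "quantile")
  expect_true(mean(q_cls$class == ref_cls$class) > 0.8)
})

test_that("period comparison reproduces the coarse-product arithmetic", {
  # 674k hours over 316 cells vs 649k hours over 335 cells
  set.seed(15)
  mk <- function(n_cells, total) {
    w <- runif(n_cells); w <- w / sum(w) * total
    effort_grid(rep(seq(0, 35.5, 0.5), length.out = n_cells),
                rep(seq(30, 45, 0.5), each = 72)[1:n_cells],
                w, resolution = 0.5)
  }
  a <- mk(316, 674000)
  b <- mk(335, 649000)
  cmp <- compare_periods(a, b)
  expect_equal(cmp$diff_hours, -25000)
  expect_equal(cmp$pct_change, -3.7, tolerance = 0.01)
  expect_equal(cmp$cells_b - cmp$cells_a, 19)

  same <- compare_periods(a, a)
  expect_equal(same$diff_hours, 0)
  expect_true(all(same$cell_diff$diff == 0))

  none <- compare_periods(a, effort_grid(numeric(0), numeric(0),
                                         numeric(0), 0.5))
  expect_equal(none$pct_change, -100)
  expect_error(compare_periods(a, effort_grid(13, 43, 1, 0.1)),
               "lattice")
})

test_that("barycentres are effort-weighted means of cell centres", {
  one <- effort_grid(13.0, 43.0, 5, 0.1)
  b1 <- monthly_barycentre(one)
  expect_equal(c(b1$lon, b1$lat), c(13.05, 43.05))

  two <- effort_grid(c(13.0, 13.2), c(43, 43), c(7, 7), 0.1)
  b2 <- monthly_barycentre(two)
  expect_equal(b2$lon, 13.15)  # midpoint of the two centres

  weighted <- effort_grid(c(13.0, 13.1), c(43, 43), c(100, 300), 0.1)
  b3 <- monthly_barycentre(weighted)
  expect_equal(b3$lon, 13.125)
  expect_equal(b3$lat, 43.05)
  expect_equal(b3$total_hours, 400)
  expect_error(monthly_barycentre(effort_grid(13, 43, 0, 0.1)),
               "positive")

  # translation equivariance
  shifted <- effort_grid(c(13.0, 13.1) + 0.5, c(43, 43) + 0.3,
                         c(100, 300), 0.1)
  b4 <- monthly_barycentre(shifted)
  expect_equal(b4$lon, b3$lon + 0.5, tolerance = 1e-9)
  expect_equal(b4$lat, b3$lat + 0.3, tolerance = 1e-9)
})

test_that("barycentre extents measure the latitudinal roaming range", {
  pts <- data.frame(gear = "PTM", year = 2020, month = 1:2,
                    lon = c(13.2, 13.4), lat = c(43.0, 44.0),
                    total_hours = c(10, 20))
  ext <- barycentre_extent(pts)
  expect_equal(ext$lat_range, 1.0)
  single <- barycentre_extent(pts[1, ])
  expect_equal(single$lat_range, 0)
  expect_equal(unname(single$bbox["lon_min"]),
               unname(single$bbox["lon_max"]))
  expect_error(barycentre_extent(pts[0, ]), "empty")

  # a wider-roaming synthetic series has the larger range
  ptm_like <- data.frame(lon = 13.3, lat = seq(42.8, 44.8, length.out = 8))
  tbb_like <- data.frame(lon = 13.3, lat = seq(43.4, 44.4, length.out = 8))
  expect_gt(barycentre_extent(ptm_like)$lat_range,
            barycentre_extent(tbb_like)$lat_range)
})
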