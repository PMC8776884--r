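# Speed-profile features, clustering, rule-based assignment and kappa.

test_that("speed histogram concentrates mass in the right bin", {
  trip <- make_trip(rep(3.2, 20))
  f <- speed_profile_features(trip)
  expect_equal(sum(f[1:30]), 1)
  expect_equal(unname(f["s3"]), 1)   # bin [3.0, 3.5)
  expect_equal(unname(f[["paired"]]), 0)  # solo vessel
  expect_error(speed_profile_features(trip[0, ]), "empty")
})

test_that("pair-trawl partners show a high paired fraction", {
  va <- vessel_spec("P1", "PTM", c(13.5, 43.5), pair_partner = "P2")
  vb <- vessel_spec("P2", "PTM", c(13.5, 43.5), pair_partner = "P1")
  pings <- simulate_ais_tracks(list(va, vb), n_days = 1, seed = 7)
  trips <- segment_trips(pings)
  for (trip in trips) {
    f <- speed_profile_features(trip, fleet_pings = pings)
    expect_gt(f[["paired"]], 0.5)
  }
})

test_that("clustering separates distinct speed modes deterministically", {
  mk_feature <- function(speed) {
    speed_profile_features(make_trip(rnorm(40, speed, 0.2)))
  }
  set.seed(8)
  feats <- rbind(t(sapply(1:10, function(i) mk_feature(3.2))),
                 t(sapply(1:10, function(i) mk_feature(8.5))))
  cl <- cluster_trips(feats, k = 2, seed = 1)
  # the two modes are reproduced exactly (up to label switching)
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
  expect_true(cl[1] != cl[11])

  expect_identical(as.integer(cl),
                   as.integer(cluster_trips(feats, k = 2, seed = 1)))
  expect_equal(as.integer(cluster_trips(feats[1:3, ] * 0 + 1, k = 1,
                                        seed = 1)),
               rep(1L, 3))
  expect_error(cluster_trips(feats[1:3, ], k = 5), "at least k")
})

test_that("assignment rules fire in the documented order", {
  # uniform speeds over 0-15 kn: no rule fires
  f_uniform <- speed_profile_features(make_trip(seq(0.1, 14.9,
                                                    length.out = 60)))
  expect_equal(assign_gear(f_uniform), "OTHER")

  f_otb <- speed_profile_features(make_trip(rep(3.2, 30)))
  expect_equal(assign_gear(f_otb), "OTB")
  f_tbb <- speed_profile_features(make_trip(rep(5.5, 30)))
  expect_equal(assign_gear(f_tbb), "TBB")

  # a paired fraction above threshold overrides the trawl-speed mode
  f_ptm <- f_otb
  f_ptm["paired"] <- 0.6
  expect_equal(assign_gear(rbind(f_ptm)), "PTM")

  # majority vote over trips; ties resolve to OTHER; order irrelevant
  feats <- rbind(f_otb, f_otb, f_tbb)
  expect_equal(assign_gear(feats), "OTB")
  expect_equal(assign_gear(feats[c(3, 1, 2), ]), "OTB")
  expect_equal(assign_gear(rbind(f_otb, f_tbb)), "OTHER")
  expect_error(assign_gear(), "no trips")
})

test_that("cohen_kappa matches hand computation and conventions", {
  expect_equal(cohen_kappa(rep(c("A", "B"), 5), rep(c("A", "B"), 5)), 1)

  # confusion matrix [[8, 2], [1, 9]]: p_o = 0.85, p_e = 0.5, kappa = 0.7
  pred <- c(rep("A", 8), rep("B", 2), rep("A", 1), rep("B", 9))
  ref <- c(rep("A", 10), rep("B", 10))
  expect_equal(cohen_kappa(pred, ref), 0.7)
  expect_equal(cohen_kappa(ref, pred), 0.7)  # symmetry

  # independence: one side constant, the other uniform over 5 gears
  set.seed(9)
  n <- 5000
  expect_lt(abs(cohen_kappa(rep("OTB", n),
                            sample(gear_labels(), n, replace = TRUE))),
            0.02)

  # both sides the same constant: chance agreement is 1, kappa is 1
  expect_equal(cohen_kappa(rep("PS", 4), rep("PS", 4)), 1)
  expect_error(cohen_kappa(c("A", "B"), c("A")), "equal length")
})

test_that("cohen_kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(10)
  pred <- sample(gear_labels(), 200, replace = TRUE)
  ref <- ifelse(runif(200) < 0.6, pred,
                sample(gear_labels(), 200, replace = TRUE))
  tab <- table(factor(pred, gear_labels()), factor(ref, gear_labels()))
  expect_equal(cohen_kappa(pred, ref),
               e1071::classAgreement(tab)$kappa)
})

test_that("synthetic vessels round-trip through the full classifier", {
  fleet <- synthetic_fleet(14, seed = 11)
  pings <- simulate_ais_tracks(fleet, n_days = 2, seed = 11)
  pred <- classify_fleet_gears(pings, seed = 11)
  truth <- attr(fleet, "gears")[pred$vessel_id]
  # every gear class is represented and recovered with excellent agreement
  expect_setequal(unique(truth), gear_labels())
  expect_gt(cohen_kappa(pred$predicted_gear, unname(truth)), 0.75)
})

test_that("registry FAO codes collapse onto the five analysis classes", {
  expect_equal(fao_to_class(c("OTB", "OTT", "PTM", "TBB", "PS", "GNS")),
               c("OTB", "OTB", "PTM", "TBB", "PS", "OTHER"))
  reg <- data.frame(vessel_id = c("V1", "V2"),
                    licensed_gear = c("OTB", "LLS"))
  path <- tempfile(fileext = ".csv")
  write.csv(reg, path, row.names = FALSE)
  got <- read_gear_registry(path)
  expect_equal(got$gear_class, c("OTB", "OTHER"))
  expect_error(read_gear_registry(write_ping_csv(reg["vessel_id"])),
               "licensed_gear")
})
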