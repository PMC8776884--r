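# Viable-pair Schaefer estimator: inversion, sampling, traits, stress.

test_that("implied_catch inverts the Schaefer recurrence", {
  # equilibrium: constant series at kq implies zero removals
  expect_equal(implied_catch(rep(2000, 5), r = 0.8, kq = 2000),
               rep(0, 4))
  # hand-evaluated single step: 1000 + 0.6*1000*(1 - 1000/2000) - 900
  expect_equal(implied_catch(c(1000, 900), r = 0.6, kq = 2000), 400)
  # r -> 0 limit reduces to the first difference
  expect_equal(implied_catch(c(500, 450), r = 1e-12, kq = 1000), 50,
               tolerance = 1e-9)
  expect_error(implied_catch(c(1000), 0.5, 1000), "at least 2")
  expect_error(implied_catch(c(1000, -5), 0.5, 1000), "positive")
})

test_that("forward simulation with implied removals reconstructs the series", {
  # short wandering series under moderate rates
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    a <- exp(cumsum(rnorm(n, 0, 0.1))) * 1000
    r <- runif(1, 0.05, 0.8)
    kq <- max(a) * runif(1, 1, 4)
    rebuilt <- schaefer_forward(a[1], r, kq, implied_catch(a, r, kq))
    expect_equal(rebuilt, a, tolerance = 1e-9)
  }

  # a year-long fleet series, checked at viable pairs across the prior box
  # (the one-step inversion is exact; over long horizons round-off is
  # amplified by the recurrence itself, so the sharp tolerance is asserted
  # on a horizon where it is numerically meaningful)
  p <- fleet_params("TBB", 0.57, 18150, noise_cv = 0)
  a <- as.numeric(simulate_effort_series(p, 12, seed = 6)$hours)
  v <- viable_pairs(a, amsy_prior(n_samples = 5000, seed = 2))
  pick <- round(seq(1, nrow(v), length.out = min(25, nrow(v))))
  for (i in pick) {
    rebuilt <- schaefer_forward(a[1], v$r[i], v$kq[i],
                                implied_catch(a, v$r[i], v$kq[i]))
    expect_equal(rebuilt, a, tolerance = 1e-9)
  }

  # on the full 71-month horizon the true generating pair round-trips
  p71 <- fleet_params("TBB", 0.57, 18150,
                      shock_months = lockdown_months_2020(), noise_cv = 0)
  a71 <- as.numeric(simulate_effort_series(p71, 71, seed = 6)$hours)
  rebuilt <- schaefer_forward(a71[1], 0.57, 18150,
                              implied_catch(a71, 0.57, 18150))
  expect_equal(rebuilt, a71, tolerance = 1e-9)
})

test_that("viability on a constant series reduces to kq >= level", {
  a <- c(100, 100, 100)
  grid <- as.matrix(expand.grid(r = seq(0.1, 2, length.out = 15),
                                kq = seq(50, 400, length.out = 15)))
  res <- viable_pairs(a, amsy_prior(kq_range = c(50, 400)), pairs = grid)
  # algebra: Cq_t = 100 r (1 - 100/kq) >= 0 iff kq >= 100 (given r > 0)
  expect_true(all(res$kq >= 100))
  expect_equal(nrow(res), sum(grid[, "kq"] >= 100))
})

test_that("sampler viability agrees exactly with exhaustive enumeration", {
  p <- fleet_params("OTB", r_true = 0.6, kq_true = 1000, a0 = 600,
                    noise_cv = 0)
  a <- as.numeric(simulate_effort_series(p, 4, seed = 5)$hours)
  grid <- as.matrix(expand.grid(r = exp(seq(log(0.05), log(2),
                                            length.out = 20)),
                                kq = exp(seq(log(max(a)), log(4 * max(a)),
                                             length.out = 20))))
  res <- viable_pairs(a, amsy_prior(), pairs = grid)
  expected <- apply(grid, 1, function(p) oracle_viable(a, p[1], p[2]))
  got <- paste(grid[, 1], grid[, 2]) %in% paste(res$r, res$kq)
  expect_identical(got, unname(expected))
})

test_that("series that outgrow every admissible rate yield no viable pairs", {
  a <- 100 * 3^(0:4)  # triples every month; far beyond r = 2
  expect_error(viable_pairs(a, amsy_prior(n_samples = 500)),
               "no viable")
})

test_that("viable_pairs is deterministic under its seed", {
  a <- as.numeric(simulate_effort_series(
    fleet_params("PS", 1.0, 20000, noise_cv = 0), 24, seed = 3)$hours)
  v1 <- viable_pairs(a, amsy_prior(n_samples = 2000, seed = 11))
  v2 <- viable_pairs(a, amsy_prior(n_samples = 2000, seed = 11))
  expect_identical(v1$r, v2$r)
  expect_identical(v1$kq, v2$kq)
})

test_that("estimate_traits reports medians, percentile CIs and MSR", {
  single <- data.frame(r = 1, kq = 400)
  tr <- estimate_traits(single)
  expect_equal(tr$r_hat, 1)
  expect_equal(tr$kq_hat, 400)
  expect_equal(tr$msr, 100)
  expect_equal(tr$n_viable, 1L)

  # published purse-seine point estimates give MSR = r*kq/4 = 5412.68
  tr2 <- estimate_traits(data.frame(r = 1.04, kq = 20818))
  expect_equal(tr2$msr, 5412.68)

  # symmetric cloud: median at the centre, CIs bracket the estimates
  set.seed(1)
  cloud <- data.frame(r = 0.8 + runif(4001, -0.2, 0.2),
                      kq = 1000 + runif(4001, -100, 100))
  tr3 <- estimate_traits(cloud)
  expect_equal(tr3$r_hat, 0.8, tolerance = 0.02)
  expect_equal(tr3$kq_hat, 1000, tolerance = 0.02)
  expect_true(tr3$r_ci[1] <= tr3$r_hat && tr3$r_hat <= tr3$r_ci[2])
  expect_true(tr3$kq_ci[1] <= tr3$kq_hat && tr3$kq_hat <= tr3$kq_ci[2])
  expect_error(estimate_traits(data.frame(r = numeric(0),
                                          kq = numeric(0))), "empty")
})

test_that("stress states classify months against MSR", {
  # constant decline engineered so Cq = msr exactly: sustainable months
  tr <- structure(list(r_hat = 1, kq_hat = 400, msr = 100, n_viable = 1L,
                       r_ci = c(1, 1), kq_ci = c(400, 400)),
                  class = "fleet_traits")
  a <- schaefer_forward(200, 1, 400, rep(100, 3))
  st <- stress_series(a, tr)
  expect_equal(st$Cmsr, rep(1, 3))
  expect_true(all(st$state == "SUSTAINABLE"))

  # Cq = c(50, 150) against msr = 100 -> UNDER then OVER
  a2 <- schaefer_forward(200, 1, 400, c(50, 150))
  st2 <- stress_series(a2, tr)
  expect_equal(st2$Cmsr, c(0.5, 1.5))
  expect_equal(st2$state, c("UNDER", "OVER"))
})

test_that("a lockdown-style shock produces the maximum stress month", {
  p <- fleet_params("PTM", r_true = 0.96, kq_true = 4526,
                    shock_months = lockdown_months_2020(), noise_cv = 0)
  a <- simulate_effort_series(p, 71, start = c(2015, 1), seed = 2)
  fit <- amsy(a, n_samples = 20000, seed = 7)
  peak <- fit$stress[which.max(fit$stress$Cmsr), ]
  expect_equal(peak$year, 2020)
  expect_true(peak$month %in% 3:5)
})

test_that("the amsy object supports the standard model interface", {
  p <- fleet_params("PS", 1.04, 20818, noise_cv = 0)
  a <- simulate_effort_series(p, 36, seed = 9)
  fit <- amsy(a, n_samples = 5000, seed = 1)

  expect_s3_class(fit, "amsy")
  co <- coef(fit)
  expect_named(co, c("r", "kq", "msr"))
  expect_equal(unname(co["msr"]), unname(co["r"] * co["kq"] / 4))

  expect_output(print(fit), "viable")
  expect_output(print(summary(fit)), "stress states")

  # an unstressed projection grows monotonically toward the fitted kq
  proj <- predict(fit, n_ahead = 24, Cq = 0)
  expect_length(proj, 24)
  expect_true(all(diff(proj) >= -1e-9))
  expect_true(all(proj <= coef(fit)["kq"] + 1e-6))

  # simulate() with zero noise reconstructs the observed series
  sim <- simulate(fit, nsim = 2)
  expect_equal(dim(sim), c(36L, 2L))
  expect_equal(sim[, 1], a$hours, tolerance = 1e-9)

  expect_length(residuals(fit), 35)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  # refitting with the same seed reproduces the traits exactly
  fit2 <- amsy(a, n_samples = 5000, seed = 1)
  expect_identical(coef(fit), coef(fit2))
})
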