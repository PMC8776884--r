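#' Fit Schaefer fleet dynamics by viable-pair Monte-Carlo sampling
#'
#' The central estimator of the package. A fleet's monthly fishing hours are
#' treated as a stock-abundance index \eqn{A_t} and assumed to follow the
#' Schaefer surplus-production dynamic
#' \deqn{A_{t+1} = A_t + r A_t (1 - A_t/kq) - Cq_t,}
#' where the "catch" \eqn{Cq_t} is the monthly reduction of fishing hours
#' imposed by external stress factors (seasonal bans, market closures,
#' decommissioning, lockdowns). `(r, kq)` pairs are drawn log-uniformly from
#' a prior box; a pair is *viable* if the implied \eqn{Cq_t} is everywhere
#' non-negative and the index never exceeds `kq`. Point estimates are the
#' medians of the viable set, with central-95% percentile intervals; the
#' maximum sustainable reduction is \eqn{MSR = r\,kq/4}, and the relative
#' stress series is \eqn{Cmsr_t = Cq_t/MSR}.
#'
#' @param series An [effort_series()] (or strictly positive numeric vector)
#'   of monthly fishing hours, length >= 2.
#' @param prior An [amsy_prior()]; defaults to `r` in (0.05, 2) per month,
#'   `kq` in `(max(A), 4 max(A))` and 100,000 draws.
#' @param ... Passed to [amsy_prior()] when `prior` is not supplied
#'   (e.g. `n_samples`, `seed`, `r_range`).
#' @return An object of class `"amsy"`: a list with components
#'   `series`, `prior`, `pairs` (viable pairs), `traits`
#'   (a `"fleet_traits"`), `stress` (a `"stress_series"`) and `call`.
#' @examples
#' a <- simulate_effort_series(
#'   fleet_params("PS", r_true = 1.04, kq_true = 20818, a0 = 10409,
#'                noise_cv = 0),
#'   n_months = 36, seed = 7)
#' fit <- amsy(a, n_samples = 2000, seed = 1)
#' coef(fit)
#' @seealso [viable_pairs()], [estimate_traits()], [stress_series()]
#' @export
amsy <- function(series, prior = NULL, ...) {
  if (is.null(prior)) prior <- amsy_prior(...)
  pairs <- viable_pairs(series, prior)
  traits <- estimate_traits(pairs)
  stress <- stress_series(series, traits)
  out <- list(series = series, prior = prior, pairs = pairs,
              traits = traits, stress = stress,
              kq_range = attr(pairs, "kq_range"),
              call = match.call())
  class(out) <- "amsy"
  out
}

#' @export
print.amsy <- function(x, ...) {
  fleet <- if (inherits(x$series, "effort_series")) x$series$fleet[1] else "?"
  cat(sprintf("Schaefer fleet-dynamics fit (viable-pair sampling), fleet %s\n",
              fleet))
  cat(sprintf("  %d months, %d viable of %d sampled pairs\n",
              length(as_hours(x$series)), x$traits$n_viable,
              attr(x$pairs, "n_sampled")))
  print(x$traits)
  over <- sum(x$stress$state == "OVER")
  cat(sprintf("  over-stressed months (Cmsr > 1): %d of %d\n",
              over, nrow(x$stress)))
  invisible(x)
}

#' @export
summary.amsy <- function(object, ...) {
  s <- list(traits = object$traits,
            n_sampled = attr(object$pairs, "n_sampled"),
            prior = object$prior,
            kq_range = object$kq_range,
            n_months = length(as_hours(object$series)),
            stress_table = table(factor(object$stress$state,
                                        c("UNDER", "SUSTAINABLE", "OVER"))),
            max_stress = object$stress[which.max(object$stress$Cmsr), ,
                                       drop = FALSE])
  class(s) <- "summary.amsy"
  s
}

#' @export
print.summary.amsy <- function(x, ...) {
  cat("Viable-pair Schaefer fit\n")
  cat(sprintf("  months fitted : %d\n", x$n_months))
  cat(sprintf("  draws         : %d (viable: %d, %.1f%%)\n", x$n_sampled,
              x$traits$n_viable, 100 * x$traits$n_viable / x$n_sampled))
  cat(sprintf("  r prior       : %.2f-%.2f /month (log-uniform)\n",
              x$prior$r_range[1], x$prior$r_range[2]))
  cat(sprintf("  kq prior      : %.0f-%.0f h (log-uniform)\n",
              x$kq_range[1], x$kq_range[2]))
  print(x$traits)
  cat("  monthly stress states:\n")
  print(x$stress_table)
  invisible(x)
}

#' @export
coef.amsy <- function(object, ...) {
  c(r = object$traits$r_hat, kq = object$traits$kq_hat,
    msr = object$traits$msr)
}

#' Project a fitted fleet forward under a stress scenario
#'
#' Forward-simulates the Schaefer dynamic from the last observed month at
#' the fitted `(r, kq)`, under a user-supplied future reduction series
#' `Cq` (default: a constant reduction equal to the fitted MSR, i.e. the
#' maximum the fleet can sustainably absorb).
#'
#' @param object An `"amsy"` fit.
#' @param n_ahead Months to project.
#' @param Cq Future monthly reductions: scalar or vector of length `n_ahead`.
#' @param ... Unused.
#' @return Numeric vector of projected monthly hours (length `n_ahead`).
#' @export
predict.amsy <- function(object, n_ahead = 12L, Cq = NULL, ...) {
  a <- as_hours(object$series)
  if (is.null(Cq)) Cq <- object$traits$msr
  Cq <- rep_len(Cq, n_ahead)
  schaefer_forward(a[length(a)], object$traits$r_hat, object$traits$kq_hat,
                   Cq)[-1L]
}

#' @export
fitted.amsy <- function(object, ...) {
  # One-step-ahead reconstruction at the fitted pair with the implied Cq:
  # exact by construction, returned for completeness.
  a <- as_hours(object$series)
  n <- length(a)
  head <- a[-n]
  head + object$traits$r_hat * head * (1 - head / object$traits$kq_hat) -
    object$stress$Cq
}

#' Deviations from the sustainable-stress expectation
#'
#' Residuals are defined against the sustainable baseline: the difference
#' between the observed month and the one-step-ahead prediction under a
#' constant reduction of MSR. Positive residuals mark months where the fleet
#' lost fewer hours than the sustainable maximum, negative residuals months
#' of excess stress.
#'
#' @param object An `"amsy"` fit.
#' @param ... Unused.
#' @return Numeric vector of length `n - 1`.
#' @export
residuals.amsy <- function(object, ...) {
  a <- as_hours(object$series)
  n <- length(a)
  head <- a[-n]
  pred <- head + object$traits$r_hat * head *
    (1 - head / object$traits$kq_hat) - object$traits$msr
  a[-1L] - pred
}

#' Simulate effort series from a fitted fleet model
#'
#' Re-simulates monthly series from the fitted Schaefer dynamic, starting at
#' the first observed month and applying the implied reduction series, with
#' optional multiplicative lognormal observation noise.
#'
#' @param object An `"amsy"` fit.
#' @param nsim Number of series to simulate.
#' @param seed Optional RNG seed.
#' @param noise_cv Observation noise coefficient of variation (0 = exact
#'   reconstruction of the latent trajectory).
#' @param ... Unused.
#' @return A matrix with `length(series)` rows and `nsim` columns.
#' @export
simulate.amsy <- function(object, nsim = 1L, seed = NULL, noise_cv = 0, ...) {
  a <- as_hours(object$series)
  latent <- schaefer_forward(a[1L], object$traits$r_hat,
                             object$traits$kq_hat, object$stress$Cq)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    sapply(seq_len(nsim), function(i) {
      if (noise_cv > 0) latent * stats::rlnorm(length(latent), 0, sdlog)
      else latent
    })
  })
}

#' Plot a viable-pair Schaefer fit
#'
#' Two panels: the viable `(r, kq)` cloud with the median estimate, and the
#' monthly relative-stress series `Cmsr` with the sustainability line at 1.
#'
#' @param x An `"amsy"` fit.
#' @param ... Passed to [plot()].
#' @export
plot.amsy <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$pairs$r, x$pairs$kq, pch = ".", log = "xy",
                 col = grDevices::grey(0.4), xlab = "r (1/month)",
                 ylab = "kq (hours)", main = "viable pairs", ...)
  graphics::points(x$traits$r_hat, x$traits$kq_hat, pch = 19, col = 2)
  idx <- seq_len(nrow(x$stress))
  graphics::plot(idx, x$stress$Cmsr, type = "l", xlab = "month index",
                 ylab = "Cmsr = Cq / MSR", main = "relative stress", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
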