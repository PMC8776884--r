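# Synthetic monthly effort series with Schaefer structure.

#' Simulation truths for a synthetic fleet
#'
#' Bundles the parameters under which [simulate_effort_series()] generates a
#' monthly effort series: the true Schaefer pair `(r, kq)`, the starting
#' level, and the stress schedule (seasonal amplitude, shock months and
#' magnitude) plus observation noise.
#'
#' @param gear Gear label of the fleet.
#' @param r_true True per-month growth rate (>= 0; 0 gives a fleet with no
#'   recovery dynamics).
#' @param kq_true True carrying capacity in hours/month (> 0).
#' @param a0 Initial monthly hours, in (0, kq_true]. Default `kq_true / 2`,
#'   the equilibrium level under a sustained reduction of exactly MSR.
#' @param seasonal_amplitude Relative amplitude of the seasonal stress
#'   sinusoid, in \[0, 1). The monthly reduction oscillates between
#'   `(1 - a) * MSR` and `(1 + a) * MSR`, with its minimum in August.
#' @param shock_months List of `c(year, month)` pairs (or a 2-column
#'   matrix/data.frame) in which an additional lockdown-style shock removes
#'   `shock_magnitude * A_t` hours.
#' @param shock_magnitude Fraction in \[0, 1\]; default 0.37.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   observation noise (median 1), in \[0, 1).
#' @return An object of class `"fleet_params"`.
#' @export
fleet_params <- function(gear, r_true, kq_true, a0 = kq_true / 2,
                         seasonal_amplitude = 0.5,
                         shock_months = list(),
                         shock_magnitude = 0.37,
                         noise_cv = 0.05) {
  check_gear(gear)
  stopifnot(is.numeric(r_true), length(r_true) == 1L, r_true >= 0,
            is.numeric(kq_true), length(kq_true) == 1L, kq_true > 0,
            is.numeric(a0), length(a0) == 1L, a0 > 0, a0 <= kq_true,
            seasonal_amplitude >= 0, seasonal_amplitude < 1,
            shock_magnitude >= 0, shock_magnitude <= 1,
            noise_cv >= 0, noise_cv < 1)
  shock_months <- normalize_shock_months(shock_months)
  structure(list(gear = gear, r_true = r_true, kq_true = kq_true, a0 = a0,
                 seasonal_amplitude = seasonal_amplitude,
                 shock_months = shock_months,
                 shock_magnitude = shock_magnitude,
                 noise_cv = noise_cv),
            class = "fleet_params")
}

normalize_shock_months <- function(x) {
  if (is.null(x) || length(x) == 0L) return(integer(0))
  if (is.data.frame(x) || is.matrix(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) as.integer(x[i, 1:2]))
  }
  vapply(x, function(p) ym_index(as.integer(p[1]), as.integer(p[2])),
         integer(1))
}

#' The March-May 2020 lockdown months
#'
#' Convenience shock schedule covering the spring-2020 lockdown period.
#'
#' @return A list of `c(year, month)` pairs.
#' @export
lockdown_months_2020 <- function() {
  list(c(2020L, 3L), c(2020L, 4L), c(2020L, 5L))
}

# Seasonal stress multiplier for calendar month m: a sinusoid with mean 1
# and minimum in August (month 8), emulating the late-summer fishing ban.
seasonal_stress_factor <- function(month, amplitude) {
  1 - amplitude * cos(2 * pi * (month - 8) / 12)
}

#' Simulate a monthly effort series under Schaefer dynamics
#'
#' Generates a fleet's monthly fishing-hour series by forward-iterating the
#' Schaefer recurrence under a stress (removal) schedule
#' \deqn{Cq_t = m \cdot MSR \cdot s(month_t) + shock_t \cdot A_t}
#' where `MSR = r_true * kq_true / 4`, `s()` is a seasonal sinusoid with
#' mean 1 and minimum in August, `m` is the `stress_mean` multiplier and
#' `shock_t` equals `shock_magnitude` in shock months and 0 otherwise.
#' Multiplicative lognormal observation noise (median 1, CV `noise_cv`) is
#' applied to the latent trajectory.
#'
#' @param params A [fleet_params()] object.
#' @param n_months Number of months to generate (>= 2).
#' @param start `c(year, month)` of the first value; default January 2015.
#' @param seed Integer RNG seed (only the observation noise is stochastic).
#' @param stress_mean Mean stress level in units of MSR. The default 0.7 is
#'   the highest level (at the default seasonal amplitude) for which all
#'   fleet parameterisations stay on a stable multi-year seasonal orbit;
#'   a sustained mean at or above 1 drives the logistic dynamic to collapse
#'   away from equilibrium. 0 switches the stress off entirely.
#' @param stress Optional explicit removal vector of length `n_months - 1`
#'   overriding the built-in schedule.
#' @return An [effort_series()] with attributes `stress` (the generated
#'   `Cq_t`, length `n_months - 1`), `latent` (the noiseless trajectory)
#'   and `params`.
#' @export
simulate_effort_series <- function(params, n_months, start = c(2015L, 1L),
                                   seed = 1L, stress_mean = 0.7,
                                   stress = NULL) {
  stopifnot(inherits(params, "fleet_params"))
  n_months <- as.integer(n_months)
  if (n_months < 2L) stop("n_months must be at least 2", call. = FALSE)
  months <- month_seq(start, n_months)
  midx <- ym_index(months$year, months$month)

  msr <- params$r_true * params$kq_true / 4
  A <- numeric(n_months)
  A[1L] <- params$a0
  Cq <- numeric(n_months - 1L)
  for (t in seq_len(n_months - 1L)) {
    if (is.null(stress)) {
      Cq[t] <- stress_mean * msr *
        seasonal_stress_factor(months$month[t], params$seasonal_amplitude)
      if (midx[t] %in% params$shock_months) {
        Cq[t] <- Cq[t] + params$shock_magnitude * A[t]
      }
    } else {
      if (length(stress) != n_months - 1L) {
        stop("stress must have length n_months - 1", call. = FALSE)
      }
      Cq[t] <- stress[t]
    }
    A[t + 1L] <- A[t] + params$r_true * A[t] * (1 - A[t] / params$kq_true) -
      Cq[t]
    if (!is.finite(A[t + 1L]) || A[t + 1L] <= 0) {
      stop("effort collapse under stress schedule at month ",
           months$year[t + 1L], "-", months$month[t + 1L],
           "; reduce stress or shock magnitude", call. = FALSE)
    }
  }

  obs <- with_seed(seed, {
    if (params$noise_cv > 0) {
      sdlog <- sqrt(log(1 + params$noise_cv^2))
      A * stats::rlnorm(n_months, meanlog = 0, sdlog = sdlog)
    } else A
  })

  out <- effort_series(params$gear, months$year, months$month, obs)
  attr(out, "stress") <- Cq
  attr(out, "latent") <- A
  attr(out, "params") <- params
  out
}

#' Synthetic Adriatic-style fleet set
#'
#' The four large-scale fleets used throughout the package's simulation
#' studies, with true growth rates and maximum sustainable hours set to the
#' published point estimates for the Adriatic purse-seine (PS), pelagic
#' pair-trawl (PTM), beam-trawl (TBB) and bottom-otter-trawl (OTB) fleets,
#' and the spring-2020 lockdown as the shock period.
#'
#' @param noise_cv Observation noise CV applied to every fleet (default 0:
#'   the noiseless design used for parameter-recovery experiments).
#' @return Named list of [fleet_params()] (names PS, PTM, TBB, OTB).
#' @export
adriatic_fleet_defaults <- function(noise_cv = 0) {
  truths <- list(PS  = c(r = 1.04, kq = 20818),
                 PTM = c(r = 0.96, kq = 4526),
                 TBB = c(r = 0.57, kq = 18150),
                 OTB = c(r = 0.56, kq = 117033))
  lapply(stats::setNames(names(truths), names(truths)), function(g) {
    fleet_params(g, r_true = unname(truths[[g]]["r"]),
                 kq_true = unname(truths[[g]]["kq"]),
                 shock_months = lockdown_months_2020(),
                 noise_cv = noise_cv)
  })
}
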