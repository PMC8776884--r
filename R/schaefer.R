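# Schaefer surplus-production primitives shared by the simulator and the
# viable-pair estimator.

#' Forward Schaefer recurrence
#'
#' Propagate an abundance index through the discrete Schaefer surplus
#' production dynamic
#' \deqn{A_{t+1} = A_t + r A_t (1 - A_t / kq) - Cq_t}
#' where `r` is the per-month growth rate, `kq` the carrying capacity on the
#' index scale (here: maximum sustainable monthly fishing hours) and `Cq_t`
#' the removal (here: the monthly reduction of fishing hours) at step t.
#'
#' @param a0 Initial index value (strictly positive).
#' @param r Growth rate per month (>= 0).
#' @param kq Carrying capacity on the index scale (> 0).
#' @param catch Numeric vector of removals `Cq_t`; the result has
#'   `length(catch) + 1` values.
#' @return Numeric vector `A_0 ... A_n`.
#' @seealso [implied_catch()] for the exact inversion.
#' @export
schaefer_forward <- function(a0, r, kq, catch) {
  stopifnot(is.numeric(a0), length(a0) == 1L, a0 > 0,
            is.numeric(r), length(r) == 1L, r >= 0,
            is.numeric(kq), length(kq) == 1L, kq > 0)
  n <- length(catch)
  A <- numeric(n + 1L)
  A[1L] <- a0
  for (t in seq_len(n)) {
    A[t + 1L] <- A[t] + r * A[t] * (1 - A[t] / kq) - catch[t]
  }
  A
}

#' Implied monthly effort reduction under the Schaefer dynamic
#'
#' Exact algebraic inversion of the Schaefer recurrence: given the observed
#' index \eqn{A_t} and a candidate pair `(r, kq)`, the removal that the
#' dynamic implies in month t is
#' \deqn{Cq_t = A_t + r A_t (1 - A_t / kq) - A_{t+1}.}
#' Forward-simulating with the returned series reproduces `A` exactly
#' (up to floating-point round-off).
#'
#' @param A An [effort_series()] or a strictly positive numeric vector of
#'   length >= 2.
#' @param r Growth rate per month (> 0; the `r = 0` limit is the plain
#'   first difference and is accepted).
#' @param kq Carrying capacity in hours (> 0).
#' @return Numeric vector of length `length(A) - 1`.
#' @export
implied_catch <- function(A, r, kq) {
  a <- as_hours(A)
  if (length(a) < 2L) stop("series must contain at least 2 months", call. = FALSE)
  if (any(a <= 0)) stop("abundance index must be strictly positive", call. = FALSE)
  stopifnot(r >= 0, kq > 0)
  n <- length(a)
  head <- a[-n]
  head + r * head * (1 - head / kq) - a[-1L]
}

# Extract the hours vector from an effort_series or pass a numeric through.
as_hours <- function(A) {
  if (inherits(A, "effort_series")) return(A$hours)
  as.numeric(A)
}

#' Prior box for the viable-pair sampler
#'
#' The sampler draws `(r, kq)` pairs log-uniformly from a rectangular prior.
#' The default growth-rate range (0.05, 2) per month is wide enough to
#' contain the recovery speeds of both slow (bottom-trawl) and fast
#' (purse-seine) fleets; the default carrying-capacity range spans from the
#' observed series maximum to four times it.
#'
#' @param r_range Length-2 vector, growth-rate bounds per month.
#' @param kq_range Length-2 vector of carrying-capacity bounds in hours, or
#'   `NULL` to use `(max(A), 4 * max(A))` of the series being fitted.
#' @param n_samples Number of Monte-Carlo draws.
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @param depletion_window Optional length-2 vector: if given, a pair is
#'   additionally required to leave the terminal relative index
#'   `A_n / kq` inside this window. Off (`NULL`) by default.
#' @return An object of class `"amsy_prior"`.
#' @export
amsy_prior <- function(r_range = c(0.05, 2), kq_range = NULL,
                       n_samples = 100000L, seed = 1L,
                       depletion_window = NULL) {
  stopifnot(length(r_range) == 2L, r_range[1] > 0, r_range[1] < r_range[2])
  if (!is.null(kq_range)) {
    stopifnot(length(kq_range) == 2L, kq_range[1] > 0,
              kq_range[1] < kq_range[2])
  }
  if (!is.null(depletion_window)) {
    stopifnot(length(depletion_window) == 2L,
              depletion_window[1] >= 0, depletion_window[1] < depletion_window[2],
              depletion_window[2] <= 1)
  }
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  structure(list(r_range = as.numeric(r_range),
                 kq_range = if (is.null(kq_range)) NULL else as.numeric(kq_range),
                 n_samples = n_samples, seed = seed,
                 depletion_window = depletion_window),
            class = "amsy_prior")
}

#' Viable (r, kq) pairs for a monthly effort series
#'
#' Draws `(r, kq)` pairs log-uniformly from the prior box and keeps the
#' pairs under which the observed series is a possible trajectory of the
#' Schaefer dynamic: every implied removal `Cq_t` must be non-negative and
#' the index must never exceed the carrying capacity (`A_t <= kq`). A large
#' viable set indicates that the series is well described by surplus
#' production dynamics.
#'
#' @param A An [effort_series()] or positive numeric vector (length >= 2).
#' @param prior An [amsy_prior()].
#' @param pairs Optional 2-column matrix (columns `r`, `kq`) of candidate
#'   pairs to screen instead of sampling; used for exhaustive grid checks.
#' @return A `data.frame` with columns `r`, `kq` of the viable pairs, with
#'   attributes `n_sampled` and `prior`.
#' @export
viable_pairs <- function(A, prior = amsy_prior(), pairs = NULL) {
  a <- as_hours(A)
  if (length(a) < 2L) stop("series must contain at least 2 months", call. = FALSE)
  if (any(a <= 0)) stop("abundance index must be strictly positive", call. = FALSE)
  stopifnot(inherits(prior, "amsy_prior"))

  kq_range <- prior$kq_range %||% c(max(a), 4 * max(a))

  if (is.null(pairs)) {
    pairs <- with_seed(prior$seed, {
      r <- exp(stats::runif(prior$n_samples,
                            log(prior$r_range[1]), log(prior$r_range[2])))
      kq <- exp(stats::runif(prior$n_samples,
                             log(kq_range[1]), log(kq_range[2])))
      cbind(r = r, kq = kq)
    })
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns (r, kq)", call. = FALSE)
    colnames(pairs) <- c("r", "kq")
  }

  keep <- screen_pairs(a, pairs[, 1L], pairs[, 2L], prior$depletion_window)
  out <- as.data.frame(pairs[keep, , drop = FALSE])
  if (nrow(out) == 0L) {
    stop("no viable (r, kq) pairs: the series does not fit Schaefer ",
         "dynamics under this prior; widen r_range/kq_range or check the ",
         "series", call. = FALSE)
  }
  attr(out, "n_sampled") <- nrow(pairs)
  attr(out, "prior") <- prior
  attr(out, "kq_range") <- kq_range
  out
}

# Vectorised viability screen. A pair is viable iff all implied Cq_t >= 0
# (up to a relative round-off guard) and max(A) <= kq.
screen_pairs <- function(a, r, kq, depletion_window = NULL,
                         chunk = 20000L) {
  n <- length(a)
  head <- a[-n]
  d <- head - a[-1L]          # A_t - A_{t+1}
  sq <- head^2
  tol <- -1e-9 * max(a)
  amax <- max(a)
  m <- length(r)
  keep <- logical(m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    ri <- r[lo:hi]
    ki <- kq[lo:hi]
    # Cq matrix: rows = pairs, cols = months
    M <- outer(ri, head, `*`) - outer(ri / ki, sq, `*`)
    M <- sweep(M, 2L, d, `+`)
    ok <- row_mins(M) >= tol & ki >= amax
    if (!is.null(depletion_window)) {
      rel <- a[n] / ki
      ok <- ok & rel >= depletion_window[1] & rel <= depletion_window[2]
    }
    keep[lo:hi] <- ok
  }
  keep
}

# Row minima without extra dependencies.
row_mins <- function(M) {
  do.call(pmin, c(as.data.frame(M), list(na.rm = FALSE)))
}

#' Fleet traits from a viable-pair set
#'
#' Point estimates are the marginal medians of the viable pairs; confidence
#' intervals are the central 95% (2.5th-97.5th percentiles). The maximum
#' sustainable reduction of fishing hours is the Schaefer maximum yield
#' \eqn{MSR = r \cdot kq / 4}, evaluated at the point estimates.
#'
#' @param viable A `data.frame` of viable pairs from [viable_pairs()].
#' @return An object of class `"fleet_traits"`: a list with `r_hat`, `r_ci`,
#'   `kq_hat`, `kq_ci`, `msr` and `n_viable`.
#' @export
estimate_traits <- function(viable) {
  if (is.null(viable) || nrow(viable) == 0L) {
    stop("empty viable-pair set", call. = FALSE)
  }
  qs <- c(0.025, 0.975)
  r_hat <- stats::median(viable$r)
  kq_hat <- stats::median(viable$kq)
  out <- list(r_hat = r_hat,
              r_ci = unname(stats::quantile(viable$r, qs)),
              kq_hat = kq_hat,
              kq_ci = unname(stats::quantile(viable$kq, qs)),
              msr = r_hat * kq_hat / 4,
              n_viable = nrow(viable))
  class(out) <- "fleet_traits"
  out
}

#' @export
print.fleet_traits <- function(x, ...) {
  cat(sprintf("Fleet traits (n_viable = %d)\n", x$n_viable))
  cat(sprintf("  r   = %.3f / month   (95%% CI %.3f-%.3f)\n",
              x$r_hat, x$r_ci[1], x$r_ci[2]))
  cat(sprintf("  kq  = %.0f hours     (95%% CI %.0f-%.0f)\n",
              x$kq_hat, x$kq_ci[1], x$kq_ci[2]))
  cat(sprintf("  MSR = %.1f hours/month (r*kq/4)\n", x$msr))
  invisible(x)
}

#' Monthly stress series relative to the maximum sustainable reduction
#'
#' Computes the implied monthly effort reduction `Cq_t` at the fitted point
#' estimates and scales it by the maximum sustainable reduction:
#' \eqn{Cmsr_t = Cq_t / MSR}. Months with `Cmsr > 1` are over-stressed
#' (the reduction exceeded what the fleet can sustainably absorb), months
#' with `Cmsr < 1` under-stressed, and `Cmsr = 1` (within 1e-9) is exactly
#' sustainable.
#'
#' @param A The [effort_series()] the traits were estimated on.
#' @param traits A [estimate_traits()] result (class `"fleet_traits"`).
#' @return A `data.frame` of class `"stress_series"` with columns `year`,
#'   `month`, `Cq`, `Cmsr`, `state`. Month t holds the reduction between
#'   months t and t+1, so the series is one shorter than `A`.
#' @export
stress_series <- function(A, traits) {
  stopifnot(inherits(traits, "fleet_traits"))
  if (traits$msr <= 0) stop("msr must be positive", call. = FALSE)
  cq <- implied_catch(A, traits$r_hat, traits$kq_hat)
  cmsr <- cq / traits$msr
  tol <- 1e-9
  state <- ifelse(abs(cmsr - 1) <= tol, "SUSTAINABLE",
                  ifelse(cmsr > 1, "OVER", "UNDER"))
  if (inherits(A, "effort_series")) {
    out <- data.frame(year = A$year[-nrow(A)], month = A$month[-nrow(A)],
                      Cq = cq, Cmsr = cmsr, state = state,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(t = seq_along(cq), Cq = cq, Cmsr = cmsr, state = state,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("stress_series", "data.frame")
  out
}
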