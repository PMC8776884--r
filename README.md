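# fleetres

Resilience assessment of fishing fleets from vessel-tracking data.

When external shocks — seasonal closures, market collapses, lockdowns —
force a fleet to fish less, how fast does it bounce back, and how much
monthly activity can it sustain at all? `fleetres` answers these questions
by treating a fleet as if it were a fish stock: the fleet's total monthly
fishing hours \(A_t\) are read as an abundance index governed by the
Schaefer surplus-production dynamic

    A[t+1] = A[t] + r * A[t] * (1 - A[t]/kq) - Cq[t]

where `r` (month⁻¹) is the fleet's intrinsic recovery speed, `kq`
(hours/month) its maximum sustainable fishing activity, and `Cq[t]` the
monthly reduction of hours imposed by the stress factors. The pair
`(r, kq)` is estimated by a viable-pair Monte-Carlo sampler: candidate
pairs are drawn log-uniformly from a prior box and kept when the
inverted dynamic yields non-negative removals with `A ≤ kq` throughout;
medians of the viable set are the point estimates. From them follow the
maximum sustainable reduction `MSR = r*kq/4` and the monthly relative
stress `Cmsr[t] = Cq[t]/MSR`, which labels each month over-stressed
(`Cmsr > 1`), under-stressed (`< 1`) or exactly sustainable.

Around this core the package provides the full analysis chain for
AIS-style vessel data:

* **ais_pipeline** — read ping tables, cut trips at reporting gaps, flag
  fishing points by gear-specific speed bands, accumulate fishing hours;
* **gear classification** — speed-profile features, k-means smoothing and
  behavioural rules assigning each vessel one of OTB / PTM / TBB / PS /
  OTHER, validated against a licence registry with Cohen's kappa;
* **effort mapping** — half-open lat-lon grids, log-normal
  low/medium/high cell classification, period comparisons and
  effort-weighted monthly barycentres;
* **ETP overlap** — species-richness grids from range polygons and the
  identification of HIGH-effort × HIGH-richness potential-impact cells;
* **synthetic data** — generators for AIS tracks, Schaefer-structured
  monthly effort series and clustered species-richness grids, so every
  stage is testable without proprietary inputs.

See the vignette (`vignettes/fleet-resilience.Rmd`) for the model,
the estimator's assumptions and its documented limitations.

## Worked example

Simulate a purse-seine-like fleet for 71 months (January 2015 – November
2020) with a spring-2020 lockdown shock, then fit the viable-pair
estimator:

```r
library(fleetres)

params <- fleet_params("PS", r_true = 1.04, kq_true = 20818,
                       shock_months = lockdown_months_2020(), noise_cv = 0)
hours <- simulate_effort_series(params, n_months = 71, seed = 1)
fit <- amsy(hours, n_samples = 100000, seed = 1)
print(fit)
#> Schaefer fleet-dynamics fit (viable-pair sampling), fleet PS
#>   71 months, 37405 viable of 100000 sampled pairs
#> Fleet traits (n_viable = 37405)
#>   r   = 1.003 / month   (95% CI 0.497-1.934)
#>   kq  = 38582 hours     (95% CI 19481-71805)
#>   MSR = 9673.5 hours/month (r*kq/4)
#>   over-stressed months (Cmsr > 1): 30 of 70
```

The 37,405 viable pairs say the series is highly consistent with
surplus-production dynamics. The recovered growth rate (1.003/month,
vs. the 1.04 used to generate the data) identifies a fast-recovering
fleet; `kq` is over-estimated, a structural property of the neutral-prior
median discussed in the vignette. The monthly stress series shows the
lockdown as the year's stress peak followed by rapid relaxation:

```r
subset(fit$stress, year == 2020 & month %in% 2:6)
#>    year month        Cq      Cmsr state
#> 62 2020     2  9948.309 1.0284123  OVER
#> 63 2020     3 13972.491 1.4444146  OVER
#> 64 2020     4  8861.748 0.9160884 UNDER
#> 65 2020     5  6249.512 0.6460470 UNDER
#> 66 2020     6  3032.953 0.3135333 UNDER
```

`coef(fit)`, `summary(fit)`, `plot(fit)`, `predict(fit, n_ahead, Cq)` and
`simulate(fit)` behave as for other fitted-model classes. A complete
synthetic run of every stage — tracks, gear kappa, effort maps,
ETP-impact cells, per-fleet fits — is one call:

```r
report <- run_pipeline(fleetres_config(seed = 1, out = "demo_out"))
report$kappa      # registry agreement of the gear classifier
report$traits$PS  # fitted traits per fleet
```

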