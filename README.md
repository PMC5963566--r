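# walrisk

Risk-based catch advice for a hunted walrus stock.

`walrisk` implements the assessment workflow used to advise quotas for the
Baffin Bay (Smith Sound) stock of Atlantic walrus, for analysts who need a
transparent, reproducible version of that calculation and for anyone
studying how sparse Arctic catch records and a handful of aerial surveys
turn into a single advised number. Everything runs from plain CSV inputs;
a synthetic-data generator with known truth makes the whole pipeline
testable offline.

## The model

The stock follows density-regulated (Pella–Tomlinson) dynamics forced by
removals:

    N_{t+1} = N_t + N_t r_max (1 − (N_t/K)^θ) − C_t

* `C_t` — total removals: landed catches with missing years filled by the
  mean of preceding documented years, corrected for underreporting and for
  struck-and-lost at 5% before 1960, ramping linearly to 30% after 1970
  (`C = landed / (1 − loss)`).
* `r_max` — maximum per-capita growth rate, obtained per parameter draw by
  solving the discrete Euler–Lotka equation
  `1 = b s_juv s_adult^(α−1) λ^−α / (1 − s_adult/λ)` for `λ = 1 + r_max`,
  with uniform priors on adult survival (0.95–0.99), first-year survival
  (0.5–0.9), age at first reproduction (5–9 yr) and birth rate (0.35–0.65).
* `K` — carrying capacity, uniform prior capped at ~5000 animals (the
  extent of shallow-water feeding habitat); `θ = 2.39` puts maximum surplus
  production near 0.6 K.
* Fitting — sampling-importance-resampling: draws from the priors are
  simulated through the catch history and weighted by a log-normal survey
  likelihood with variance `log(1 + cv²)`.
* Advice — each posterior draw is projected 5 years under a candidate
  constant catch; the advised quota is the largest catch for which the
  stock increases with probability ≥ 0.70.

## Worked example

Generate a synthetic stock with known truth (K = 4000, 20% depleted in
1900), degrade its catch record the way the real one is degraded, survey it
five times at cv = 0.05, and assess it:

```r
library(walrisk)

dem   <- demographic_params(s_adult = 0.97, s_juv = 0.7, alpha = 7, b = 0.5)
truth <- dynamics_params(rmax = rmax(dem), K = 4000, theta = 2.39,
                         N_start = 3200, start_year = 1900)
sc    <- scenario_config(seed = 101, truth = truth, years = c(1900, 2015),
                         policy = "era_sparse", level = 110,
                         survey_years = c(2006, 2008, 2010, 2012, 2014),
                         survey_cvs = 0.05)
tt   <- generate_truth(sc)
sv   <- generate_surveys(tt$trajectory, sc$survey_years, sc$survey_cvs,
                         seed = 101)
post <- fit_sir(default_priors(), tt$removals, sv, n_draws = 50000,
                seed = 202)
post
#> posterior ensemble: 50000 retained draws of 50000 prior draws
#>   ESS: 3174.7  seed: 202
#>   weighted mean K: 4031  weighted mean rmax: 0.122
advise_quota(post, projection_spec(horizon = 5, criterion = 0.70))
#> advised quota: 115 animals/yr (P(increase over 5 yr) >= 0.70)
```

The posterior mean of K (4031) recovers the truth (4000) within 1%, and the
advised quota of 115 animals/yr is the largest constant catch whose 5-year
projection still shows an increase in at least 70% of posterior draws.
Compare that with subsistence demand: with 60 full-time hunters each
needing about 12 walruses a year to feed a 16-dog team,

```r
subsistence_demand(60)                                   # 720
q <- smith_sound_quotas()
demand_gap(720, q$quota[q$year == 2017])                 # 635 at the 85 quota
```

demand exceeds any defensible quota several-fold — the tension the
assessment quantifies.

A command-line wrapper is installed with the package
(`system.file("exec", "assess", package = "walrisk")`), with subcommands
`reconstruct`, `fit`, `simulate`, `advise`, `demand`, `simulate-scenario`
and `run` (full pipeline; writes `removals.csv`, `posterior.csv`,
`risk_curve.csv`, `advice.json`).

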