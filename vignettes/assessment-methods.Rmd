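---
title: "Assessment methods: model, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessment methods: model, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walrisk)
```

## The problem

Walrus hunting in Northwest Greenland has been managed by quota since 2007,
with advice derived from a stock assessment rather than from direct census.
The assessment must work with what exists: a catch record that is sporadic
before the Piniarneq reporting system (1993), rough struck-and-lost
assumptions, a few recent aerial-survey abundance estimates with CVs, and
life-history knowledge borrowed from comparable stocks. `walrisk`
implements that calculation end to end, from raw catch records to an
advised quota, with every assumption exposed as a parameter.

## Population model

A single unstructured stock with generalised-logistic (Pella–Tomlinson)
density regulation, forced by removals:

$$N_{t+1} = \max\!\left(0,\; N_t + N_t\, r_{max}\left(1 -
  (N_t/K)^{\theta}\right) - C_t\right).$$

The choice of a surplus-production model over an age-structured one is
deliberate: age- and sex-specific vital rates for this stock are too
sparsely sampled to matter, and all demographic detail is collapsed into a
single maximum growth rate $r_{max}$ (below). Dynamics are deterministic
conditional on parameters; all uncertainty is parametric and enters through
the prior ensemble. Abundance is continuous-valued and zero is absorbing.

Key parameters:

| parameter | units | default / prior | rationale |
|---|---|---|---|
| $K$ | animals | U(1000, 5000] | shallow-water (<50 m) feeding habitat caps the plausible stock near 5000 |
| $\theta$ | — | 2.39 (fixed) | puts maximum surplus production at $(1+\theta)^{-1/\theta} \approx 0.6K$, conventional for marine mammals |
| $d_0 = N_{1900}/K$ | — | U(0.3, 1.0) | broad ignorance about pre-exploitation depletion |
| $r_{max}$ | yr$^{-1}$ | derived per draw | see next section |

`msyl_fraction(theta)` exposes the MSYL diagnostic; it is not used by the
advice rule itself.

## From life-history priors to $r_{max}$

The priors are independent uniforms on the printed ranges: adult survival
$s \in [0.95, 0.99]$, first-year survival $s_0 \in [0.5, 0.9]$, age at
first reproduction $\alpha \in \{5,\dots,9\}$ (uniform on the integers),
and birth rate $b \in [0.35, 0.65]$ per mature individual (the population
is modelled unsexed; no sex-ratio split is applied because none is given).
Each draw is mapped to a growth multiplier by the discrete Euler–Lotka
equation under geometric adult survival (senescence ignored):

$$1 = b\, s_0\, s^{\alpha-1} \lambda^{-\alpha} \big/ (1 - s/\lambda),
\qquad \lambda > s,$$

solved by bracketed bisection to $10^{-10}$; $r_{max} = \lambda - 1$. With
$b = 0$ there is no root above $s$ and $\lambda = s$ (pure survival decay)
is returned. The collapse of the printed ranges through Euler–Lotka is this
package's own design choice — the source does not state how its model maps
demography to growth — and it is validated in the test suite against an
independent oracle: the dominant eigenvalue of the explicit age-structured
(Leslie) projection matrix truncated at 200 age classes agrees with the
bisection root to better than $10^{-6}$ across the whole prior range.

## Catch-series reconstruction

Removals before the model sees them:

1. **Fill** — undocumented years take the arithmetic mean of the preceding
   *documented* years (never of previously filled values), by default all
   of them within the same reporting era (pre/post 1993, so the sparse
   historical record and the systematic modern one do not contaminate each
   other; a finite window is available). A missing year with no documented
   predecessor is an error, not a guess. Filled values carry an
   `extrapolated` flag; downstream code currently does not down-weight
   them.
2. **Underreporting** — a single multiplicative factor $\geq 1$, default 1:
   no magnitude is established, so the default is a deliberate no-op knob.
3. **Struck-and-lost** — losses are a fraction $L(y)$ of all animals
   struck, so removals are $landed/(1 - L(y))$, *not* $landed \times
   (1+L)$. $L$ is 5% before 1960 (harpoon-first hunting), 30% from 1970 on
   (motorised hunting), linear in between; "gradually" is not quantified in
   the source, so the ramp shape is a declared choice. The schedule is
   continuous at both endpoints and monotone in year.

## Fitting: sampling-importance-resampling

The fit draws `n_draws` parameter vectors from the priors, simulates each
through the removals history from 1900, and weights by the survey
likelihood: survey estimates with CV are treated as log-normal
absolute-abundance indices, $\log \hat N \sim \mathrm{Normal}(\log N_y,\,
\log(1+cv^2))$, with no bias factor (the surveys are designed to be the
largest available estimates). Weights are normalised likelihoods; the
effective sample size $1/\sum w_i^2$ is reported, and an optional
equal-weight resample gives a compact posterior. SIR was chosen over MCMC
because the source specifies priors-as-ranges and a statistical "safe
space" rather than an estimator; SIR is embarrassingly parallel,
bit-reproducible under a seed, and every step is oracle-checkable.

Numerical notes:

* A draw whose trajectory hits zero before a survey year has likelihood
  $-\infty$ and weight exactly zero. If *every* draw does, the fit aborts
  with a degenerate-posterior error rather than returning noise.
* Weights never become exactly uniform as $cv \to \infty$, because the
  log-normal variance grows only as $\log(1+cv^2)$; the tests assert
  monotone flattening rather than exact uniformity.
* The whole fit is vectorised across draws (one year-loop, no per-draw
  simulation), so 50,000 draws through a 116-year history take seconds.

## Projection and the advice rule

Each retained draw is projected `horizon` years (default 5) from its own
terminal abundance under a constant candidate catch. "The stock increases"
means the endpoint abundance strictly exceeds the starting abundance —
endpoint, not year-over-year, and strict, so a stock held exactly at
equilibrium does not count as increasing. (Whether the operative rule
evaluates the endpoint or an expectation is not stated anywhere we know of;
endpoint is the declared choice.) The advised quota is the largest catch on
an integer grid (default 0–200) whose probability of increase, weighted
over draws, meets the criterion (default 0.70). Because dynamics are
deterministic per draw, the risk curve is exactly non-increasing in catch —
common random numbers are inherent, not an implementation trick.

Future quota catches are **not** loss-inflated by default: a quota binds
landed animals, and struck-and-lost in future hunts is a different policy
question. A `future_loss` switch applies the final-year loss rate to
projected catches for sensitivity analysis.

The subsistence arithmetic (`per_hunter_need()`, `subsistence_demand()`,
`demand_gap()`) is deliberately trivial: one walrus feeds a 16-dog team
for about a month, hence 12 per hunter-year, hence 720 for 60 hunters —
kept in the package because the gap between that number and any defensible
quota is the substantive finding the assessment frames.

## The synthetic-data generator

`scenario_config()` / `generate_truth()` / `generate_surveys()` /
`degrade_catch_record()` emulate the statistical structure the assessment
assumes: a density-regulated trajectory under a catch policy (constant,
proportional, or era-mimicking sparse with log-normal year effects around a
level of ~110 animals, matching the scale of the historical record), a
sparse catch record with ~30% of years missing and era-dependent loss
rates, and a handful of recent log-normal surveys. Survey noise is
mean-unbiased in natural space ($\varepsilon \sim
N(-\tfrac12\sigma^2, \sigma^2)$), matching how point estimates with CVs are
reported. The generator's first catch year is always documented so the
record remains reconstructable.

What a green end-to-end test establishes: that the pipeline recovers known
parameters from data generated *by its own assumed process*. It does not
establish that the process matches real walrus data — real surveys may be
biased indices, real loss rates are era-guesses, and real catch gaps are
not missing at random. The headline real-data outputs of the operative
assessment (the fitted trajectory and the advice series) depend on survey
estimates that are not public, and are out of scope by design; the shipped
quota table is documentary input, not a fitting target.

## Known limitations

* No spatial structure, no Canada–Greenland allocation, no migration.
* No demographic or environmental stochasticity; a constant $K$.
* Calves lost when their mothers are taken are not modelled beyond the
  struck-and-lost fraction.
* The underreporting factor is a knob with a neutral default, not an
  estimate.
* Quota advice is a single constant catch; no multi-year optimisation.
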