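#' Survey observations
#'
#' @param year Survey years.
#' @param estimate Point estimates of abundance (> 0).
#' @param cv Coefficients of variation (> 0).
#' @return A `data.frame` of class `survey_obs`.
#' @export
survey_obs <- function(year, estimate, cv) {
  if (any(estimate <= 0)) stop("survey estimates must be > 0")
  if (any(cv <= 0)) stop("survey cv must be > 0")
  out <- data.frame(year = as.integer(year), estimate = as.numeric(estimate),
                    cv = as.numeric(cv))
  class(out) <- c("survey_obs", "data.frame")
  out
}

#' Log-normal survey log-likelihood of a trajectory
#'
#' Surveys are treated as absolute-abundance indices with log-normal error:
#' each contributes the log-density of `log(estimate)` under
#' `Normal(log(N_year), log(1 + cv^2))`. A zero predicted abundance gives
#' `-Inf`.
#'
#' @param traj A `trajectory` (data.frame with `year`, `N`).
#' @param surveys A [survey_obs()] data.frame.
#' @return The summed log-likelihood (scalar).
#' @export
log_likelihood <- function(traj, surveys) {
  idx <- match(surveys$year, traj$year)
  if (anyNA(idx))
    stop("survey year(s) outside trajectory: ",
         paste(surveys$year[is.na(idx)], collapse = ", "))
  N <- traj$N[idx]
  sdlog <- sqrt(log(1 + surveys$cv^2))
  ll <- ifelse(N > 0,
               stats::dnorm(log(surveys$estimate), log(pmax(N, .Machine$double.xmin)),
                            sdlog, log = TRUE),
               -Inf)
  sum(ll)
}

# draw n parameter vectors from the prior ranges (caller seeds the RNG)
.sample_priors <- function(priors, n) {
  u <- function(r) stats::runif(n, r[1], r[2])
  avals <- seq.int(priors$alpha[1], priors$alpha[2])
  alpha <- avals[sample.int(length(avals), n, replace = TRUE)]
  data.frame(s_adult = u(priors$s_adult), s_juv = u(priors$s_juv),
             alpha = alpha, b = u(priors$b), K = u(priors$K),
             d0 = u(priors$d0), theta = u(priors$theta))
}

# vectorised simulation of all draws through the removals forcing;
# returns predicted abundance at survey years plus the terminal abundance
.simulate_draws <- function(draws, removals, survey_years) {
  n <- nrow(draws)
  N <- draws$d0 * draws$K
  pred <- matrix(NA_real_, n, length(survey_years))
  yrs <- removals$year
  hit <- match(yrs, survey_years)
  for (t in seq_along(yrs)) {
    if (!is.na(hit[t])) pred[, hit[t]] <- N
    N <- pmax(0, N + N * draws$rmax * (1 - (N / draws$K)^draws$theta) -
                removals$removals[t])
  }
  end_year <- yrs[length(yrs)] + 1L
  j <- which(survey_years == end_year)
  if (length(j)) pred[, j] <- N
  list(pred = pred, N_final = N)
}

#' Fit the assessment by sampling-importance-resampling
#'
#' Draws parameters from independent uniform priors (demographic ranges,
#' carrying capacity, initial depletion), collapses each draw's demography
#' into `rmax` via the Euler-Lotka equation, simulates the stock through the
#' removals history, and weights each draw by the log-normal survey
#' likelihood. Optionally resamples to an equal-weight ensemble.
#'
#' @param priors A [default_priors()] specification.
#' @param removals A `removals_series` from [reconstruct()] (the forcing;
#'   simulation starts at its first year).
#' @param surveys A [survey_obs()] data.frame (at least one row). Years must
#'   lie within the simulated range.
#' @param n_draws Number of prior draws (>= `resample`).
#' @param resample If > 0, size of the equal-weight resampled ensemble.
#' @param seed Integer RNG seed; the fit is reproducible given it.
#' @return An object of class `posterior_ensemble`: list with `draws` (one
#'   row per retained draw, including `rmax` and terminal abundance
#'   `N_current`), `weights` (summing to 1), `ess`, `seed`, `n_draws`.
#' @export
fit_sir <- function(priors, removals, surveys, n_draws = 50000,
                    resample = 0, seed = 1) {
  stopifnot(inherits(priors, "prior_spec"), n_draws >= 1,
            resample <= n_draws)
  if (nrow(surveys) < 1) stop("at least one survey observation is required")
  end_year <- removals$year[nrow(removals)] + 1L
  if (any(surveys$year < removals$year[1] | surveys$year > end_year))
    stop("survey year(s) outside the simulated range")
  set.seed(seed)
  draws <- .sample_priors(priors, n_draws)
  draws$rmax <- .lambda_max_vec(draws$s_adult, draws$s_juv,
                                draws$alpha, draws$b) - 1
  sim <- .simulate_draws(draws, removals, surveys$year)
  sdlog <- sqrt(log(1 + surveys$cv^2))
  ll <- rowSums(vapply(seq_len(nrow(surveys)), function(j) {
    N <- sim$pred[, j]
    ifelse(N > 0,
           stats::dnorm(log(surveys$estimate[j]),
                        log(pmax(N, .Machine$double.xmin)),
                        sdlog[j], log = TRUE),
           -Inf)
  }, numeric(n_draws)))
  if (all(!is.finite(ll)))
    stop("degenerate posterior: no draw is compatible with the surveys; ",
         "increase n_draws or widen the priors")
  w <- exp(ll - max(ll[is.finite(ll)]))
  w[!is.finite(ll)] <- 0
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  draws$N_start <- draws$d0 * draws$K
  draws$N_current <- sim$N_final
  if (resample > 0) {
    idx <- sample.int(n_draws, resample, replace = TRUE, prob = w)
    draws <- draws[idx, , drop = FALSE]
    rownames(draws) <- NULL
    w <- rep(1 / resample, resample)
  }
  structure(list(draws = draws, weights = w, ess = ess, seed = seed,
                 n_draws = n_draws,
                 start_year = removals$year[1], end_year = end_year,
                 resampled = resample > 0),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat("posterior ensemble:", nrow(x$draws), "retained draws of", x$n_draws,
      "prior draws\n  ESS:", round(x$ess, 1),
      " seed:", x$seed,
      "\n  weighted mean K:",
      round(sum(x$weights * x$draws$K), 1),
      " weighted mean rmax:",
      signif(sum(x$weights * x$draws$rmax), 3), "\n")
  invisible(x)
}
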