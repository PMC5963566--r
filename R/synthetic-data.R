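#' Scenario configuration for synthetic assessments
#'
#' Bundles a known-truth parameterisation with a catch policy and a survey
#' design, so every pipeline stage can be tested against ground truth
#' without any external data.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param truth A [dynamics_params()] object (the true stock).
#' @param years `c(start, end)` calendar years of the catch history.
#' @param policy Catch policy: `"constant"` (fixed annual removals),
#'   `"proportional"` (removals = `rate * N`), or `"era_sparse"` (era-mean
#'   removals with log-normal year effects, mimicking a sparse historical
#'   record).
#' @param level Constant removals (policy `"constant"`) or era mean
#'   (policy `"era_sparse"`).
#' @param rate Harvest rate for policy `"proportional"`.
#' @param cv_policy Log-normal year-effect CV for `"era_sparse"`
#'   (default 0.3).
#' @param survey_years Years with a survey observation.
#' @param survey_cvs CVs of those surveys (recycled).
#' @param missing_fraction Fraction of years masked as undocumented by
#'   [degrade_catch_record()] (in `[0, 1)`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, truth, years = c(1900, 2015),
                            policy = c("constant", "proportional",
                                       "era_sparse"),
                            level = 100, rate = 0.03, cv_policy = 0.3,
                            survey_years = integer(), survey_cvs = 0.2,
                            missing_fraction = 0.3) {
  policy <- match.arg(policy)
  stopifnot(inherits(truth, "dynamics_params"),
            missing_fraction >= 0, missing_fraction < 1,
            years[1] < years[2])
  structure(list(seed = seed, truth = truth, years = years, policy = policy,
                 level = level, rate = rate, cv_policy = cv_policy,
                 survey_years = as.integer(survey_years),
                 survey_cvs = rep_len(survey_cvs, length(survey_years)),
                 missing_fraction = missing_fraction),
            class = "scenario_config")
}

#' Generate the true trajectory and removals of a scenario
#'
#' Deterministic given the config seed. If the policy drives the stock
#' extinct before the end of the range, the result carries attribute
#' `extinct = TRUE` rather than failing.
#'
#' @param config A [scenario_config()].
#' @return List with `trajectory` (the truth) and `removals`
#'   (a `removals_series`).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  yrs <- seq.int(config$years[1], config$years[2])
  tr <- config$truth
  tr$start_year <- config$years[1]
  set.seed(config$seed)
  if (config$policy == "proportional") {
    N <- numeric(length(yrs) + 1L)
    rem <- numeric(length(yrs))
    N[1] <- tr$N_start
    for (t in seq_along(yrs)) {
      rem[t] <- config$rate * N[t]
      N[t + 1L] <- step(N[t], tr, rem[t])
    }
    traj <- data.frame(year = c(yrs, yrs[length(yrs)] + 1L), N = N)
    class(traj) <- c("trajectory", "data.frame")
  } else {
    rem <- switch(config$policy,
      constant = rep(config$level, length(yrs)),
      era_sparse = {
        sdlog <- sqrt(log(1 + config$cv_policy^2))
        config$level * exp(stats::rnorm(length(yrs), -sdlog^2 / 2, sdlog))
      })
    traj <- simulate_trajectory(tr, data.frame(year = yrs, removals = rem))
  }
  removals <- data.frame(year = yrs, landed = NA_real_, removals = rem,
                         extrapolated = FALSE)
  class(removals) <- c("removals_series", "data.frame")
  out <- list(trajectory = traj, removals = removals)
  attr(out, "extinct") <- any(traj$N == 0)
  out
}

#' Generate log-normally noisy survey observations of a trajectory
#'
#' `estimate = N_year * exp(eps)` with
#' `eps ~ Normal(-log(1 + cv^2)/2, log(1 + cv^2))`, i.e. mean-unbiased in
#' natural space, matching how survey point estimates with CVs are reported.
#'
#' @param traj A `trajectory`.
#' @param years Survey years (within the trajectory).
#' @param cvs CVs (recycled over `years`).
#' @param seed Integer seed.
#' @return A [survey_obs()] data.frame (empty for empty `years`).
#' @export
generate_surveys <- function(traj, years, cvs, seed = 1) {
  if (!length(years))
    return(survey_obs(integer(), numeric(), numeric())[0, ])
  idx <- match(years, traj$year)
  if (anyNA(idx)) stop("survey year(s) outside trajectory")
  cvs <- rep_len(cvs, length(years))
  set.seed(seed)
  sdlog <- sqrt(log(1 + cvs^2))
  eps <- stats::rnorm(length(years), -sdlog^2 / 2, sdlog)
  survey_obs(years, traj$N[idx] * exp(eps), cvs)
}

#' Degrade a removals series into a sparse reported-catch record
#'
#' Converts removals back to landed counts through the loss-schedule inverse
#' (`landed = removals * (1 - loss_rate)`), then masks a random subset of
#' years as undocumented. The first year is always kept documented so the
#' record remains reconstructable. Reconstruction with the true schedule
#' recovers removals on documented years, enabling round-trip tests.
#'
#' @param removals A `removals_series` (or data.frame with `year`,
#'   `removals`).
#' @param missing_fraction Fraction of years masked, in `[0, 1)`.
#' @param seed Integer seed.
#' @param schedule The [loss_schedule()] used for the inversion.
#' @return A [reported_catch()] record.
#' @export
degrade_catch_record <- function(removals, missing_fraction = 0.3, seed = 1,
                                 schedule = loss_schedule()) {
  stopifnot(missing_fraction >= 0, missing_fraction < 1)
  landed <- removals$removals * (1 - loss_rate(removals$year, schedule))
  set.seed(seed)
  mask <- stats::runif(length(landed)) < missing_fraction
  mask[1] <- FALSE
  landed[mask] <- NA_real_
  reported_catch(removals$year, landed,
                 source = ifelse(removals$year < 1993, "HLG", "Piniarneq"))
}
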