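#' Projection specification for catch advice
#'
#' The management rule: future catches should with at least 70% probability
#' allow the stock to increase over a 5-year projection.
#'
#' @param horizon Projection length in years (>= 1; default 5).
#' @param criterion Required probability of increase (default 0.70).
#' @param catch_grid Candidate annual catches (non-negative integers,
#'   default 0:200).
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(horizon = 5, criterion = 0.70,
                            catch_grid = 0:200) {
  stopifnot(horizon >= 1, criterion > 0, criterion <= 1,
            all(catch_grid >= 0))
  structure(list(horizon = as.integer(horizon), criterion = criterion,
                 catch_grid = sort(unique(as.integer(catch_grid)))),
            class = "projection_spec")
}

#' Probability that the stock increases under a constant catch
#'
#' Each posterior draw is projected `horizon` years forward from its
#' terminal abundance under a constant annual removal of `catch` (quotas
#' bind landed animals, so future catches are not loss-inflated by
#' default), and the weighted fraction of draws with strictly higher
#' endpoint abundance is returned.
#'
#' @param ensemble A `posterior_ensemble` from [fit_sir()].
#' @param catch Constant annual catch (>= 0).
#' @param spec A [projection_spec()].
#' @param future_loss Optional loss fraction applied to future catches
#'   (default 0 = quota semantics); if > 0, removals are
#'   `catch / (1 - future_loss)`.
#' @return Probability of increase in `[0, 1]`.
#' @export
prob_increase <- function(ensemble, catch, spec = projection_spec(),
                          future_loss = 0) {
  stopifnot(inherits(ensemble, "posterior_ensemble"), catch >= 0,
            future_loss >= 0, future_loss < 1)
  d <- ensemble$draws
  if (nrow(d) == 0L) stop("empty ensemble")
  rem <- catch / (1 - future_loss)
  N <- d$N_current
  for (t in seq_len(spec$horizon))
    N <- pmax(0, N + N * d$rmax * (1 - (N / d$K)^d$theta) - rem)
  sum(ensemble$weights * (N > d$N_current))
}

#' Risk curve over a catch grid
#'
#' [prob_increase()] on every grid point with the same ensemble; because
#' the dynamics are deterministic per draw, the curve is exactly
#' non-increasing in catch.
#'
#' @inheritParams prob_increase
#' @return A `data.frame` of class `risk_curve` with columns
#'   `catch, p_increase`.
#' @export
risk_curve <- function(ensemble, spec = projection_spec(), future_loss = 0) {
  if (!length(spec$catch_grid)) stop("empty catch grid")
  p <- vapply(spec$catch_grid, prob_increase, numeric(1),
              ensemble = ensemble, spec = spec, future_loss = future_loss)
  out <- data.frame(catch = spec$catch_grid, p_increase = p)
  class(out) <- c("risk_curve", "data.frame")
  out
}

#' Advise a quota under the probability-of-increase rule
#'
#' The largest catch on the grid whose probability of increase meets the
#' criterion; 0 if none does. The grid must cover 0.
#'
#' @inheritParams prob_increase
#' @return An object of class `quota_advice`: list with `quota`,
#'   `criterion`, `horizon`, and the full `curve`.
#' @export
advise_quota <- function(ensemble, spec = projection_spec(),
                         future_loss = 0) {
  if (!0 %in% spec$catch_grid) stop("catch grid must cover 0")
  curve <- risk_curve(ensemble, spec, future_loss)
  ok <- curve$p_increase >= spec$criterion
  quota <- if (any(ok)) max(curve$catch[ok]) else 0L
  structure(list(quota = as.integer(quota), criterion = spec$criterion,
                 horizon = spec$horizon, curve = curve),
            class = "quota_advice")
}

#' @export
print.quota_advice <- function(x, ...) {
  cat("advised quota:", x$quota, "animals/yr",
      sprintf("(P(increase over %d yr) >= %.2f)\n", x$horizon, x$criterion))
  invisible(x)
}

#' Annual walruses needed per hunter
#'
#' One large walrus feeds a 16-dog team for a little less than a month, so a
#' hunter feeding a team on walrus alone needs about one walrus per month:
#' 12 per year.
#'
#' @param months_per_walrus Months one walrus feeds a full team (default 1).
#' @param months_per_year Months of feeding per year (default 12).
#' @return Walruses per hunter per year.
#' @export
per_hunter_need <- function(months_per_walrus = 1, months_per_year = 12) {
  stopifnot(months_per_walrus > 0, months_per_year > 0)
  months_per_year / months_per_walrus
}

#' Annual subsistence demand for walrus
#'
#' @param n_hunters Number of full-time hunters.
#' @param walruses_per_hunter_year Walruses each hunter needs per year
#'   (default 12; see [per_hunter_need()]).
#' @return Total annual demand (animals).
#' @export
#' @examples
#' subsistence_demand(60)   # 720
subsistence_demand <- function(n_hunters, walruses_per_hunter_year = 12) {
  stopifnot(n_hunters >= 0, walruses_per_hunter_year >= 0)
  n_hunters * walruses_per_hunter_year
}

#' Gap between subsistence demand and quota
#'
#' Positive when demand exceeds the quota.
#'
#' @param demand Annual demand (>= 0).
#' @param quota Annual quota (>= 0).
#' @return `demand - quota` (signed).
#' @export
demand_gap <- function(demand, quota) {
  stopifnot(demand >= 0, quota >= 0)
  demand - quota
}
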