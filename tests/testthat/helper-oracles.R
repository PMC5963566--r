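# Independent oracles used across test files. These re-derive results by
# brute force (enumeration, truncated sums, explicit matrices, grid search)
# and never call the code paths they check.

# dominant eigenvalue of the explicit age-structured (Leslie) projection
# matrix, pre-breeding census, truncated at max_age classes
leslie_lambda <- function(s_adult, s_juv, alpha, b, max_age = 200L) {
  M <- matrix(0, max_age, max_age)
  M[1, alpha:max_age] <- b * s_juv
  M[cbind(2:max_age, 1:(max_age - 1L))] <- s_adult
  max(Re(eigen(M, only.values = TRUE)$values))
}

# truncated life-table sum for the net reproductive rate
r0_truncated <- function(s_adult, s_juv, alpha, b, max_age = 500L) {
  ages <- alpha:max_age
  sum(b * s_juv * s_adult^(ages - 1))
}

# explicit re-fill of missing years: mean of the `window` most recent
# documented years (era-restricted), enumerated year by year
fill_oracle <- function(years, landed, window, era_boundary = 1993) {
  out <- landed
  for (i in seq_along(years)) {
    if (!is.na(out[i])) next
    doc <- which(!is.na(landed[seq_len(i - 1L)]))
    same_era <- doc[(years[doc] < era_boundary) == (years[i] < era_boundary)]
    if (length(same_era)) doc <- same_era
    if (identical(window, "all")) use <- doc
    else use <- utils::tail(doc, window)
    out[i] <- mean(landed[use])
  }
  out
}

# fixture posterior ensemble built directly from given draws
make_ensemble <- function(rmax, K, theta, N_current, weights = NULL) {
  n <- max(length(rmax), length(K), length(theta), length(N_current))
  d <- data.frame(rmax = rep_len(rmax, n), K = rep_len(K, n),
                  theta = rep_len(theta, n),
                  N_current = rep_len(N_current, n))
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  structure(list(draws = d, weights = w, ess = 1 / sum(w^2), seed = 0L,
                 n_draws = n, resampled = FALSE),
            class = "posterior_ensemble")
}

# standard synthetic assessment used by inference / acceptance tests:
# known truth K = 4000, initial depletion 0.8 at 1900, demographic truth
# inside the prior ranges, era-mimicking sparse catches, 5 precise surveys
standard_scenario <- function(seed = 101, survey_cv = 0.05) {
  dem <- demographic_params(0.97, 0.7, 7, 0.5)
  truth <- dynamics_params(rmax(dem), K = 4000, theta = 2.39,
                           N_start = 0.8 * 4000, start_year = 1900)
  scenario_config(seed = seed, truth = truth, years = c(1900, 2015),
                  policy = "era_sparse", level = 110,
                  survey_years = c(2006, 2008, 2010, 2012, 2014),
                  survey_cvs = survey_cv, missing_fraction = 0.3)
}
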