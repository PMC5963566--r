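make_traj <- function(years, N) {
  out <- data.frame(year = years, N = N)
  class(out) <- c("trajectory", "data.frame")
  out
}

test_that("log_likelihood is the summed log-normal survey density", {
  traj <- make_traj(2000:2010, seq(2800, 3300, length.out = 11))

  # independent density evaluation
  sv <- survey_obs(2005, 2500, 0.2)
  sdlog <- sqrt(log(1 + 0.2^2))
  want <- dnorm(log(2500), log(traj$N[traj$year == 2005]), sdlog, log = TRUE)
  expect_equal(log_likelihood(traj, sv), want)

  # additivity over surveys
  sv2 <- survey_obs(c(2005, 2009), c(2500, 3100), c(0.2, 0.1))
  expect_equal(log_likelihood(traj, sv2),
               log_likelihood(traj, sv2[1, ]) + log_likelihood(traj, sv2[2, ]))

  # the term is maximised when the prediction equals the estimate
  lls <- vapply(seq(1500, 4000, by = 25), function(N)
    log_likelihood(make_traj(2005, N), sv), numeric(1))
  expect_equal(seq(1500, 4000, by = 25)[which.max(lls)], 2500)

  # extinct prediction is impossible under any survey
  expect_equal(log_likelihood(make_traj(2005, 0), sv), -Inf)
  expect_error(log_likelihood(traj, survey_obs(1990, 2500, 0.2)),
               "outside trajectory")
})

test_that("fit_sir with point-mass priors returns the prior, full ESS", {
  sc <- standard_scenario()
  truth <- generate_truth(sc)
  sv <- generate_surveys(truth$trajectory, sc$survey_years, sc$survey_cvs,
                         seed = sc$seed)
  pm <- prior_spec(s_adult = c(0.97, 0.97), s_juv = c(0.7, 0.7),
                   alpha = c(7L, 7L), b = c(0.5, 0.5),
                   K = c(4000, 4000), d0 = c(0.8, 0.8))
  post <- fit_sir(pm, truth$removals, sv, n_draws = 200, seed = 1)
  expect_equal(post$ess, 200)
  expect_true(all(post$draws$K == 4000))
  expect_equal(post$weights, rep(1 / 200, 200))
})

test_that("the likelihood flattens as the survey cv grows", {
  # zero-removal forcing so no draw goes extinct: every draw must then get
  # positive weight, and the weights approach uniformity as cv -> Inf
  # (exactly uniform is unreachable because the log-normal variance grows
  # only as log(1 + cv^2))
  rem <- data.frame(year = 1900:2014, removals = 0)
  class(rem) <- c("removals_series", "data.frame")
  sv_at <- function(cv) survey_obs(2010, 3000, cv)
  spread <- vapply(c(1, 1e3, 1e6), function(cv) {
    post <- fit_sir(default_priors(), rem, sv_at(cv), n_draws = 500,
                    seed = 2)
    diff(range(post$weights)) / mean(post$weights)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[3], 0.2)
})

test_that("fit_sir is reproducible and its weights are a distribution", {
  sc <- standard_scenario()
  truth <- generate_truth(sc)
  sv <- generate_surveys(truth$trajectory, sc$survey_years, sc$survey_cvs,
                         seed = sc$seed)
  a <- fit_sir(default_priors(), truth$removals, sv, n_draws = 2000,
               resample = 500, seed = 9)
  b <- fit_sir(default_priors(), truth$removals, sv, n_draws = 2000,
               resample = 500, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_identical(a$weights, b$weights)
  expect_equal(sum(a$weights), 1, tolerance = 1e-12)
  expect_true(a$ess >= 1 && a$ess <= 2000)
  expect_equal(nrow(a$draws), 500)
})

test_that("the posterior concentrates as surveys sharpen", {
  sds <- vapply(c(0.2, 0.05, 0.01), function(cv) {
    sc <- standard_scenario(survey_cv = cv)
    truth <- generate_truth(sc)
    sv <- generate_surveys(truth$trajectory, sc$survey_years, sc$survey_cvs,
                           seed = sc$seed)
    post <- fit_sir(default_priors(), truth$removals, sv,
                    n_draws = 8000, seed = 31)
    mu <- sum(post$weights * post$draws$K)
    sqrt(sum(post$weights * (post$draws$K - mu)^2))
  }, numeric(1))
  expect_true(all(diff(sds) <= 0))
})

test_that("with an uninformative survey the resample reproduces the prior", {
  rem <- data.frame(year = 1900:2014, removals = 0)
  class(rem) <- c("removals_series", "data.frame")
  sv <- survey_obs(2010, 3000, 1e6)   # effectively no information
  post <- fit_sir(default_priors(), rem, sv,
                  n_draws = 10000, resample = 10000, seed = 4)
  pr <- default_priors()
  for (nm in c("s_adult", "s_juv", "b", "K", "d0")) {
    ks <- suppressWarnings(
      ks.test(post$draws[[nm]], "punif", pr[[nm]][1], pr[[nm]][2]))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("an impossible survey history raises the degenerate error", {
  sc <- standard_scenario()
  truth <- generate_truth(sc)
  rem <- truth$removals
  rem$removals <- rem$removals + 1e5    # drives every draw extinct
  sv <- survey_obs(2014, 3000, 0.05)
  expect_error(fit_sir(default_priors(), rem, sv, n_draws = 100, seed = 1),
               "degenerate posterior")
})
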