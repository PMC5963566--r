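test_that("prob_increase covers the certain-growth and certain-loss cases", {
  ens <- make_ensemble(rmax = c(0.05, 0.08), K = 4000, theta = 2.39,
                       N_current = c(2000, 2500))
  expect_equal(prob_increase(ens, 0), 1)
  # catch beyond any possible stock wipes out every draw
  expect_equal(prob_increase(ens, ceiling(4000 * 1.08) + 1), 0)
  expect_error(prob_increase(make_ensemble(numeric(), numeric(), numeric(),
                                           numeric()), 0),
               "empty ensemble")
})

test_that("prob_increase equals the per-draw enumeration oracle", {
  set.seed(12)
  n <- 100
  ens <- make_ensemble(rmax = runif(n, 0.02, 0.12),
                       K = runif(n, 2500, 5000), theta = 2.39,
                       N_current = runif(n, 800, 4000),
                       weights = runif(n))
  spec <- projection_spec(horizon = 5)
  for (catch in c(0, 45, 85)) {
    want <- 0
    for (i in seq_len(n)) {
      N0 <- ens$draws$N_current[i]
      N <- N0
      for (t in 1:5)
        N <- max(0, N + N * ens$draws$rmax[i] *
                   (1 - (N / ens$draws$K[i])^2.39) - catch)
      if (N > N0) want <- want + ens$weights[i]
    }
    expect_equal(prob_increase(ens, catch, spec), want)
  }
})

test_that("risk_curve is exactly non-increasing and matches pointwise calls", {
  set.seed(13)
  ens <- make_ensemble(rmax = runif(50, 0.02, 0.12),
                       K = runif(50, 2500, 5000), theta = 2.39,
                       N_current = runif(50, 800, 4000))
  spec <- projection_spec(catch_grid = c(0, 25, 50, 75, 100))
  curve <- risk_curve(ens, spec)
  expect_true(all(diff(curve$p_increase) <= 0))
  expect_true(all(curve$p_increase >= 0 & curve$p_increase <= 1))
  for (i in seq_len(nrow(curve)))
    expect_equal(curve$p_increase[i],
                 prob_increase(ens, curve$catch[i], spec))
  # singleton grid on a growing ensemble
  grow <- make_ensemble(0.08, 4000, 2.39, 2000)
  expect_equal(risk_curve(grow, projection_spec(catch_grid = 0))$p_increase, 1)
})

test_that("advise_quota implements the largest-admissible-catch rule", {
  set.seed(14)
  ens <- make_ensemble(rmax = runif(200, 0.02, 0.12),
                       K = runif(200, 2500, 5000), theta = 2.39,
                       N_current = runif(200, 800, 4000))
  spec <- projection_spec(horizon = 5, criterion = 0.70, catch_grid = 0:200)
  adv <- advise_quota(ens, spec)
  curve <- adv$curve
  # linear-scan oracle over the grid
  ok <- curve$catch[curve$p_increase >= 0.70]
  expect_equal(adv$quota, if (length(ok)) max(ok) else 0L)
  # rule correctness at the boundary
  i <- match(adv$quota, curve$catch)
  expect_gte(curve$p_increase[i], 0.70)
  if (adv$quota < max(curve$catch))
    expect_lt(curve$p_increase[i + 1L], 0.70)
  # advice is monotone non-increasing in the criterion
  strict <- advise_quota(ens, projection_spec(criterion = 1.0))
  expect_lte(strict$quota, adv$quota)
  expect_error(advise_quota(ens, projection_spec(catch_grid = 5:10)),
               "cover 0")
})

test_that("increase means strictly greater than the starting abundance", {
  # every draw at equilibrium: zero catch cannot produce an increase
  eq <- make_ensemble(rmax = 0.08, K = 4000, theta = 2.39, N_current = 4000)
  expect_equal(prob_increase(eq, 0), 0)
  expect_equal(advise_quota(eq)$quota, 0L)

  # removals exactly equal to each draw's surplus hold N fixed: no increase
  N <- 2000; r <- 0.08; K <- 4000; th <- 2.39
  surplus <- N * r * (1 - (N / K)^th)
  ens <- make_ensemble(r, K, th, N)
  # a hair above the surplus can never produce a strict increase; a hair
  # below always does (the exact knife edge is float-noise sensitive)
  expect_equal(prob_increase(ens, surplus + 1e-9), 0)
  expect_equal(prob_increase(ens, surplus * 0.999), 1)
})

test_that("future catches can optionally carry a loss inflation", {
  ens <- make_ensemble(0.05, 4000, 2.39, 3000)
  p0 <- prob_increase(ens, 100, future_loss = 0)
  # inflating removals can only lower the probability of increase
  expect_lte(prob_increase(ens, 100, future_loss = 0.3), p0)
})

test_that("subsistence demand arithmetic", {
  expect_equal(per_hunter_need(), 12)
  expect_equal(subsistence_demand(60), 720)
  expect_equal(subsistence_demand(0), 0)
  expect_equal(subsistence_demand(1), 12)
  expect_equal(demand_gap(720, 85), 635)
  expect_equal(demand_gap(100, 100), 0)
  expect_lt(demand_gap(50, 85), 0)
})
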