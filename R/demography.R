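#' Life-history parameters
#'
#' The four demographic quantities the assessment treats as uncertain, with
#' prior support on the ranges used for this stock: annual adult survival
#' 0.95-0.99, first-year survival 0.5-0.9, age at first reproduction 5-9
#' years, and birth rate 0.35-0.65 offspring per mature individual per year.
#' The population is modelled unsexed, so `b` counts recruits per mature
#' individual without a sex-ratio split.
#'
#' @param s_adult Annual adult survival probability, in (0, 1).
#' @param s_juv First-year survival probability, in (0, 1].
#' @param alpha Age at first reproduction (integer years >= 1).
#' @param b Birth rate (>= 0).
#' @param check_support If `TRUE`, additionally require the values to lie in
#'   the assessment's prior ranges.
#' @return An object of class `demographic_params`.
#' @export
demographic_params <- function(s_adult, s_juv, alpha, b,
                               check_support = FALSE) {
  stopifnot(s_adult > 0, s_adult < 1, s_juv > 0, s_juv <= 1,
            alpha >= 1, alpha == floor(alpha), b >= 0)
  if (check_support) {
    pr <- default_priors()
    ok <- s_adult >= pr$s_adult[1] && s_adult <= pr$s_adult[2] &&
      s_juv >= pr$s_juv[1] && s_juv <= pr$s_juv[2] &&
      alpha >= pr$alpha[1] && alpha <= pr$alpha[2] &&
      b >= pr$b[1] && b <= pr$b[2]
    if (!ok) stop("parameters outside the assessment prior support")
  }
  structure(list(s_adult = s_adult, s_juv = s_juv,
                 alpha = as.integer(alpha), b = b),
            class = "demographic_params")
}

#' Uniform prior specification
#'
#' Independent uniform ranges for every uncertain quantity of the
#' assessment. Defaults are the ranges used for this stock: survival and
#' birth-rate bounds from comparable stocks, carrying capacity capped near
#' 5000 animals by the extent of shallow-water feeding grounds, and a broad
#' uniform initial depletion. Degenerate ranges (`lo == hi`) are allowed
#' and give point-mass priors.
#'
#' @param s_adult,s_juv,b `c(lo, hi)` ranges for the demographic rates.
#' @param alpha `c(lo, hi)` for age at first reproduction; sampled uniform
#'   on the integers `lo:hi`.
#' @param K Carrying-capacity range (animals); `hi` honours the ~5000 cap.
#' @param d0 Initial-depletion (`N_start / K`) range.
#' @param theta Density-dependence shape; fixed scalar or `c(lo, hi)` range.
#' @return A named list of `c(lo, hi)` ranges (class `prior_spec`).
#' @export
prior_spec <- function(s_adult = c(0.95, 0.99), s_juv = c(0.5, 0.9),
                       alpha = c(5L, 9L), b = c(0.35, 0.65),
                       K = c(1000, 5000), d0 = c(0.3, 1.0), theta = 2.39) {
  if (length(theta) == 1L) theta <- c(theta, theta)
  pr <- list(s_adult = as.numeric(s_adult), s_juv = as.numeric(s_juv),
             alpha = as.integer(alpha), b = as.numeric(b),
             K = as.numeric(K), d0 = as.numeric(d0),
             theta = as.numeric(theta))
  for (nm in names(pr)) {
    r <- pr[[nm]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop("prior range for ", nm, " must be a finite c(lo, hi), lo <= hi")
  }
  stopifnot(all(theta > 0), all(pr$s_adult > 0), all(pr$s_adult < 1),
            all(pr$s_juv > 0), all(pr$s_juv <= 1), all(pr$b >= 0),
            all(pr$K > 0), all(pr$d0 > 0), all(pr$d0 <= 1))
  structure(pr, class = "prior_spec")
}

#' @rdname prior_spec
#' @param K_lo,K_hi,d0_lo,d0_hi Scalar convenience forms of `K` and `d0`.
#' @export
default_priors <- function(K_lo = 1000, K_hi = 5000,
                           d0_lo = 0.3, d0_hi = 1.0, theta = 2.39) {
  prior_spec(K = c(K_lo, K_hi), d0 = c(d0_lo, d0_hi), theta = theta)
}

#' Net reproductive rate
#'
#' Expected lifetime recruit production per recruit,
#' `R0 = b * s_juv * s_adult^(alpha - 1) / (1 - s_adult)`, under geometric
#' adult survival (senescence ignored).
#'
#' @param params A [demographic_params()] object.
#' @return `R0` (dimensionless).
#' @export
net_reproductive_rate <- function(params) {
  with(params, b * s_juv * s_adult^(alpha - 1) / (1 - s_adult))
}

# Euler-Lotka discrepancy, vectorised over lambda and parameters:
# f(lambda) = b*s_juv*s_adult^(alpha-1)*lambda^(-alpha)/(1-s_adult/lambda) - 1
.el_f <- function(lambda, s_adult, s_juv, alpha, b) {
  b * s_juv * s_adult^(alpha - 1) * lambda^(-alpha) /
    (1 - s_adult / lambda) - 1
}

# vectorised bracketed bisection for the Euler-Lotka root, lambda > s_adult
.lambda_max_vec <- function(s_adult, s_juv, alpha, b, tol = 1e-10) {
  n <- max(length(s_adult), length(s_juv), length(alpha), length(b))
  s_adult <- rep_len(s_adult, n); s_juv <- rep_len(s_juv, n)
  alpha <- rep_len(alpha, n); b <- rep_len(b, n)
  lam <- rep(NA_real_, n)
  dead <- b <= 0
  lam[dead] <- s_adult[dead]
  if (all(dead)) return(lam)
  i <- which(!dead)
  lo <- s_adult[i] * (1 + 1e-12) + 1e-12   # f -> +Inf as lambda -> s_adult+
  hi <- rep(2, length(i))
  bad <- .el_f(hi, s_adult[i], s_juv[i], alpha[i], b[i]) > 0
  while (any(bad)) {            # walruses never double yearly, but be safe
    hi[bad] <- hi[bad] * 2
    bad <- .el_f(hi, s_adult[i], s_juv[i], alpha[i], b[i]) > 0
  }
  for (it in seq_len(80L)) {
    mid <- (lo + hi) / 2
    pos <- .el_f(mid, s_adult[i], s_juv[i], alpha[i], b[i]) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    if (max(hi - lo) < tol) break
  }
  lam[i] <- (lo + hi) / 2
  lam
}

#' Maximum annual growth multiplier from the Euler-Lotka equation
#'
#' Solves `1 = b * s_juv * s_adult^(alpha-1) * lambda^-alpha /
#' (1 - s_adult/lambda)` for the dominant growth multiplier `lambda >
#' s_adult` by bracketed bisection (tolerance 1e-10). With `b = 0` there is
#' no root above `s_adult` and the pure-survival decay rate `s_adult` is
#' returned.
#'
#' @param params A [demographic_params()] object.
#' @param max_age Unused numerical truncation bound kept for interface
#'   symmetry with age-structured checks; must be at least `alpha + 50`.
#' @return The dominant annual multiplier `lambda`.
#' @export
lambda_max <- function(params, max_age = 200L) {
  stopifnot(inherits(params, "demographic_params"), max_age >= params$alpha + 50)
  with(params, .lambda_max_vec(s_adult, s_juv, alpha, b))
}

#' Maximum per-capita growth rate
#'
#' `rmax = lambda_max(params) - 1`; the growth rate at vanishing density
#' used by the surplus-production dynamics.
#'
#' @inheritParams lambda_max
#' @return `rmax` (per year).
#' @export
rmax <- function(params, max_age = 200L) {
  lambda_max(params, max_age) - 1
}
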