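#' Density-regulated dynamics parameters
#'
#' Generalised-logistic (Pella-Tomlinson) surplus production: the per-capita
#' growth rate declines from `rmax` at vanishing density to zero at carrying
#' capacity `K`, with shape `theta` controlling where surplus production
#' peaks (see [msyl_fraction()]). Default `theta = 2.39` places that peak
#' near 0.6 K, a conventional marine-mammal choice.
#'
#' @param rmax Maximum per-capita growth rate (> -1).
#' @param K Carrying capacity (animals), not exceeding `K_cap`.
#' @param theta Density-dependence shape (> 0).
#' @param N_start Initial abundance, in (0, K].
#' @param start_year Calendar year of `N_start`.
#' @param K_cap Upper plausibility cap on `K` (default 5000, from the extent
#'   of shallow-water feeding habitat).
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(rmax, K, theta = 2.39, N_start = K,
                            start_year = 1900, K_cap = 5000) {
  stopifnot(rmax > -1, theta > 0, K > 0, N_start > 0, N_start <= K)
  if (K > K_cap) stop("K exceeds the configured cap (", K_cap, " animals)")
  structure(list(rmax = rmax, K = K, theta = theta, N_start = N_start,
                 start_year = start_year),
            class = "dynamics_params")
}

#' One annual update of the stock
#'
#' `N' = max(0, N + N * rmax * (1 - (N/K)^theta) - removals)`. Zero is
#' absorbing; abundance is continuous-valued.
#'
#' @param N Current abundance (>= 0); vectorised.
#' @param params A [dynamics_params()] object (or any list with `rmax`, `K`,
#'   `theta`).
#' @param removals Animals removed this year (>= 0); vectorised.
#' @return Next abundance.
#' @export
step <- function(N, params, removals = 0) {
  stopifnot(all(N >= 0), all(removals >= 0))
  pmax(0, N + N * params$rmax * (1 - (N / params$K)^params$theta) - removals)
}

#' Simulate an abundance trajectory under a removals forcing
#'
#' Deterministic iteration of [step()] from `params$N_start` at
#' `params$start_year` through the final forcing year; the trajectory has
#' one more year than the forcing.
#'
#' @param params A [dynamics_params()] object.
#' @param removals A `removals_series` (data.frame with `year`, `removals`)
#'   contiguous from `params$start_year`, or a bare numeric vector taken to
#'   start at `start_year`.
#' @return A `data.frame` of class `trajectory` with columns `year, N`.
#' @export
simulate_trajectory <- function(params, removals) {
  if (is.data.frame(removals)) {
    yrs <- removals$year
    if (yrs[1] != params$start_year ||
        any(diff(yrs) != 1))
      stop("forcing gap: removals must be contiguous from start_year")
    rem <- removals$removals
  } else {
    rem <- as.numeric(removals)
    yrs <- seq.int(params$start_year, length.out = length(rem))
  }
  N <- numeric(length(rem) + 1L)
  N[1] <- params$N_start
  for (t in seq_along(rem)) N[t + 1L] <- step(N[t], params, rem[t])
  out <- data.frame(year = c(yrs, yrs[length(yrs)] + 1L), N = N)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Depletion level maximising surplus production (MSYL)
#'
#' For generalised-logistic dynamics the surplus `N * rmax * (1 - (N/K)^theta)`
#' peaks at `N*/K = (1 + theta)^(-1/theta)`: one half for the logistic
#' (`theta = 1`), about 0.6 at the default `theta = 2.39`.
#'
#' @param theta Density-dependence shape (> 0); vectorised.
#' @return MSYL as a fraction of carrying capacity.
#' @export
msyl_fraction <- function(theta) {
  stopifnot(all(theta > 0))
  (1 + theta)^(-1 / theta)
}
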