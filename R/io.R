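#' Read a reported-catch CSV
#'
#' Expected header: `year,landed,documented,source`; missing landed counts
#' are empty fields. Duplicate years and negative counts are rejected with
#' the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A [reported_catch()] record.
#' @export
read_catches <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "landed", "documented", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catches file missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$year) | df$year != floor(df$year)))
    stop("non-integer year at row ",
         which(!is.finite(df$year) | df$year != floor(df$year))[1])
  bad <- which(!is.na(df$landed) & df$landed < 0)
  if (length(bad)) stop("negative landed count at row ", bad[1])
  dup <- which(duplicated(df$year))
  if (length(dup)) stop("duplicate year at row ", dup[1])
  reported_catch(df$year, df$landed, as.logical(df$documented), df$source)
}

#' Write a reported-catch CSV
#'
#' @param series A [reported_catch()] record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catches <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a survey CSV
#'
#' Expected header: `year,estimate,cv`; positive estimates and CVs enforced.
#'
#' @param path Path to the CSV file.
#' @return A [survey_obs()] data.frame.
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "estimate", "cv")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("surveys file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$estimate) | df$estimate <= 0)
  if (length(bad)) stop("non-positive estimate at row ", bad[1])
  bad <- which(!is.finite(df$cv) | df$cv <= 0)
  if (length(bad)) stop("non-positive cv at row ", bad[1])
  survey_obs(df$year, df$estimate, df$cv)
}

#' Write a survey CSV
#'
#' @param surveys A [survey_obs()] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surveys <- function(surveys, path) {
  utils::write.csv(as.data.frame(surveys), path, row.names = FALSE)
  invisible(path)
}

#' Full assessment configuration
#'
#' Defaults are the assessment's printed constants: 5%/30% loss rates with a
#' 1960-1970 ramp, the demographic prior ranges, the ~5000-animal carrying
#' capacity cap, the 70% probability-of-increase criterion and the 5-year
#' horizon.
#'
#' @param priors A [default_priors()] specification.
#' @param loss A [loss_schedule()].
#' @param reconstruction A [reconstruction_config()].
#' @param projection A [projection_spec()].
#' @param years Assessment year range `c(start, end)` of the catch history.
#' @param n_draws,resample SIR sample sizes.
#' @param seed Integer RNG seed.
#' @return An object of class `assessment_config`.
#' @export
assessment_config <- function(priors = default_priors(),
                              loss = loss_schedule(),
                              reconstruction = reconstruction_config(),
                              projection = projection_spec(),
                              years = c(1900, 2015),
                              n_draws = 50000, resample = 5000, seed = 1) {
  structure(list(priors = priors, loss = loss,
                 reconstruction = reconstruction, projection = projection,
                 years = as.integer(years), n_draws = as.integer(n_draws),
                 resample = as.integer(resample), seed = as.integer(seed)),
            class = "assessment_config")
}

#' Write / read an assessment configuration (JSON)
#'
#' Round-trips losslessly: `read_config(write_config(cfg, path))` restores
#' an identical configuration.
#'
#' @param config An [assessment_config()].
#' @param path File path.
#' @return `path` invisibly (`write_config`); an `assessment_config`
#'   (`read_config`).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "assessment_config"))
  x <- rapply(unclass(config), identity, how = "list")
  jsonlite::write_json(x, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- x$priors
  assessment_config(
    priors = prior_spec(s_adult = pr$s_adult, s_juv = pr$s_juv,
                        alpha = pr$alpha, b = pr$b, K = pr$K,
                        d0 = pr$d0, theta = pr$theta),
    loss = do.call(loss_schedule, x$loss),
    reconstruction = do.call(reconstruction_config, x$reconstruction),
    projection = projection_spec(x$projection$horizon,
                                 x$projection$criterion,
                                 x$projection$catch_grid),
    years = x$years, n_draws = x$n_draws, resample = x$resample,
    seed = x$seed)
}

#' Run the full assessment pipeline
#'
#' reconstruct -> fit -> advise. Writes `removals.csv`, `posterior.csv`,
#' `risk_curve.csv` and `advice.json` under `out_dir`; logs the seed, the
#' effective sample size and a config hash to stderr.
#'
#' @param config An [assessment_config()].
#' @param catches_path,surveys_path Input CSVs (see [read_catches()],
#'   [read_surveys()]).
#' @param out_dir Output directory (created if absent).
#' @return The [advise_quota()] result, invisibly.
#' @export
run_pipeline <- function(config, catches_path, surveys_path, out_dir) {
  stopifnot(inherits(config, "assessment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  catches <- stage("read", read_catches(catches_path))
  surveys <- stage("read", read_surveys(surveys_path))
  removals <- stage("reconstruct",
                    reconstruct(catches, config$loss, config$reconstruction,
                                config$years))
  utils::write.csv(as.data.frame(removals),
                   file.path(out_dir, "removals.csv"), row.names = FALSE)
  post <- stage("fit",
                fit_sir(config$priors, removals, surveys,
                        n_draws = config$n_draws,
                        resample = config$resample, seed = config$seed))
  pdf_out <- cbind(as.data.frame(post$draws), weight = post$weights)
  utils::write.csv(pdf_out, file.path(out_dir, "posterior.csv"),
                   row.names = FALSE)
  advice <- stage("advise", advise_quota(post, config$projection))
  utils::write.csv(as.data.frame(advice$curve),
                   file.path(out_dir, "risk_curve.csv"), row.names = FALSE)
  cfg_json <- jsonlite::toJSON(rapply(unclass(config), identity,
                                      how = "list"), digits = NA)
  jsonlite::write_json(list(quota = advice$quota,
                            criterion = advice$criterion,
                            horizon = advice$horizon,
                            seed = config$seed, ess = post$ess,
                            risk_curve = advice$curve),
                       file.path(out_dir, "advice.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("seed=%d ess=%.1f config_sha=%s quota=%d",
                  config$seed, post$ess,
                  substr(.digest_string(as.character(cfg_json)), 1, 12),
                  advice$quota))
  invisible(advice)
}

#' Quota history for the Greenland side of Smith Sound
#'
#' The annual walrus quotas set by the Greenland Government since their
#' introduction in 2007, with the NAMMCO catch advice where one was issued.
#' Documentary input for the demand-gap arithmetic; not used by the fit.
#'
#' @return A `data.frame` with columns `year, quota, advice` (advice `NA`
#'   where none was recorded).
#' @export
#' @examples
#' q <- smith_sound_quotas()
#' demand_gap(subsistence_demand(60), q$quota[q$year == 2017])
smith_sound_quotas <- function() {
  utils::read.csv(system.file("extdata", "smith_sound_quotas.csv",
                              package = "walrisk"))
}

# tiny polynomial content hash; avoids a digest dependency for the config log
.digest_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
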