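#' Struck-and-lost schedule
#'
#' Hunting losses (animals fatally struck but not retrieved) changed with the
#' introduction of motorised vessels: roughly 5% before 1960, when walrus were
#' harpooned before being shot, rising to an assumed 30% for catches after
#' 1970. The schedule is piecewise linear: `early_rate` before `ramp_start`,
#' `late_rate` from `ramp_end` on, linear in between.
#'
#' @param early_rate Loss fraction before the ramp (default 0.05).
#' @param late_rate Loss fraction after the ramp (default 0.30).
#' @param ramp_start First year of the transition (default 1960).
#' @param ramp_end Year the late rate is fully in force (default 1970).
#' @return An object of class `loss_schedule`.
#' @seealso [loss_rate()], [to_removals()]
#' @export
#' @examples
#' sched <- loss_schedule()
#' loss_rate(c(1950, 1965, 1980), sched)
loss_schedule <- function(early_rate = 0.05, late_rate = 0.30,
                          ramp_start = 1960, ramp_end = 1970) {
  stopifnot(is.numeric(early_rate), is.numeric(late_rate),
            length(early_rate) == 1L, length(late_rate) == 1L)
  if (!(early_rate >= 0 && early_rate <= late_rate && late_rate < 1))
    stop("loss schedule requires 0 <= early_rate <= late_rate < 1")
  if (ramp_start > ramp_end)
    stop("ramp_start must not exceed ramp_end")
  structure(list(early_rate = early_rate, late_rate = late_rate,
                 ramp_start = as.integer(ramp_start),
                 ramp_end = as.integer(ramp_end)),
            class = "loss_schedule")
}

#' Struck-and-lost rate for a given year
#'
#' @param year Calendar year (vectorised).
#' @param schedule A [loss_schedule()].
#' @return Loss fraction(s) in `[0, 1)`.
#' @export
loss_rate <- function(year, schedule = loss_schedule()) {
  stopifnot(inherits(schedule, "loss_schedule"))
  with(schedule, {
    interp <- if (ramp_end == ramp_start) early_rate else
      early_rate + (late_rate - early_rate) *
        (year - ramp_start) / (ramp_end - ramp_start)
    ifelse(year <= ramp_start, early_rate,
           ifelse(year >= ramp_end, late_rate, interp))
  })
}

#' Reconstruction configuration
#'
#' @param fill_window Number of most recent documented years averaged when
#'   filling a missing year, or `"all"` for every preceding documented year
#'   (restricted to the same reporting era; see Details).
#' @param underreport_factor Multiplicative correction (>= 1) applied to
#'   landed counts; default 1 (no correction) since no magnitude is
#'   established for this stock.
#' @param era_boundary Calendar year splitting the sporadic early reporting
#'   era from the systematic (Piniarneq) era; fills never mix eras.
#'   Default 1993.
#'
#' @details Missing years are filled with the arithmetic mean of the
#'   `fill_window` most recent *documented* (never extrapolated) years within
#'   the same reporting era, so the well-documented modern record does not
#'   leak backwards into the sparse historical record or vice versa.
#' @return An object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(fill_window = "all", underreport_factor = 1,
                                  era_boundary = 1993) {
  if (!(identical(fill_window, "all") ||
        (is.numeric(fill_window) && length(fill_window) == 1L &&
         fill_window >= 1 && fill_window == floor(fill_window))))
    stop("fill_window must be \"all\" or an integer >= 1")
  if (!is.numeric(underreport_factor) || underreport_factor < 1)
    stop("underreport_factor must be >= 1")
  if (is.numeric(fill_window)) fill_window <- as.integer(fill_window)
  structure(list(fill_window = fill_window,
                 underreport_factor = underreport_factor,
                 era_boundary = as.integer(era_boundary)),
            class = "reconstruction_config")
}

#' Reported-catch records
#'
#' Constructor/validator for per-year reported catches. `landed` is `NA`
#' exactly when the year is undocumented.
#'
#' @param year Integer calendar years, unique.
#' @param landed Non-negative counts, `NA` where undocumented.
#' @param documented Logical; defaults to `!is.na(landed)`.
#' @param source Reporting source per year: one of `"HLG"`, `"Piniarneq"`,
#'   `"detailed_report"`, `"special_report"`.
#' @return A `data.frame` of class `reported_catch` with columns
#'   `year, landed, documented, source`.
#' @export
reported_catch <- function(year, landed, documented = !is.na(landed),
                           source = "HLG") {
  year <- as.integer(year)
  if (anyDuplicated(year))
    stop("duplicate year(s) in catch record: ",
         paste(unique(year[duplicated(year)]), collapse = ", "))
  landed <- as.numeric(landed)
  if (any(landed < 0, na.rm = TRUE)) stop("landed counts must be >= 0")
  documented <- as.logical(documented)
  if (any(documented != !is.na(landed)))
    stop("documented flag must match presence of a landed value")
  source <- rep_len(as.character(source), length(year))
  ok_src <- c("HLG", "Piniarneq", "detailed_report", "special_report")
  if (!all(source %in% ok_src))
    stop("unknown source tag(s): ",
         paste(unique(setdiff(source, ok_src)), collapse = ", "))
  out <- data.frame(year = year, landed = landed,
                    documented = as.logical(documented), source = source,
                    stringsAsFactors = FALSE)
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reported_catch", "data.frame")
  out
}

# reporting era of a year given the configured boundary
.catch_era <- function(year, era_boundary) {
  ifelse(year < era_boundary, "pre", "post")
}

#' Fill missing years of a catch record
#'
#' Every year of `range` gets a landed value; undocumented years are filled
#' with the mean of the preceding documented years (era-restricted window,
#' see [reconstruction_config()]). Documented values are never altered.
#'
#' @param series A [reported_catch()] record.
#' @param config A [reconstruction_config()].
#' @param range Integer vector of two years `c(start, end)` (inclusive).
#' @return A `data.frame` with columns `year, landed, extrapolated, source`.
#' @export
fill_missing_years <- function(series, config = reconstruction_config(),
                               range) {
  stopifnot(inherits(series, "reported_catch"),
            inherits(config, "reconstruction_config"))
  if (anyDuplicated(series$year)) stop("duplicate years in input series")
  years <- seq.int(range[1], range[2])
  landed <- rep(NA_real_, length(years))
  src <- rep("special_report", length(years))
  idx <- match(series$year, years)
  keep <- !is.na(idx) & series$documented
  landed[idx[keep]] <- series$landed[keep]
  src[idx[!is.na(idx)]] <- series$source[!is.na(idx)]
  # documented years anywhere before the range also inform the first fills
  pre <- series[series$documented & series$year < range[1], , drop = FALSE]
  hist_year <- pre$year
  hist_landed <- pre$landed
  extrap <- is.na(landed)
  for (i in seq_along(years)) {
    if (!is.na(landed[i])) {
      hist_year <- c(hist_year, years[i])
      hist_landed <- c(hist_landed, landed[i])
      next
    }
    era <- .catch_era(years[i], config$era_boundary)
    ok <- .catch_era(hist_year, config$era_boundary) == era
    if (!any(ok)) {
      # fall back to any documented history rather than fail mid-range,
      # but an empty history is a hard error
      ok <- rep(TRUE, length(hist_year))
    }
    if (!length(hist_year))
      stop("unfillable range: no documented year precedes ", years[i])
    cand <- hist_landed[ok]
    if (!identical(config$fill_window, "all")) {
      k <- min(length(cand), config$fill_window)
      cand <- cand[seq.int(length(cand) - k + 1L, length(cand))]
    }
    landed[i] <- mean(cand)
  }
  data.frame(year = years, landed = landed, extrapolated = extrap,
             source = src, stringsAsFactors = FALSE)
}

#' Landed catch to total removals
#'
#' Struck-and-lost is a fraction of all animals struck, so true removals are
#' `landed * underreport_factor / (1 - loss_rate(year))`.
#'
#' @param landed Non-negative landed count(s).
#' @param year Matching year(s).
#' @param schedule A [loss_schedule()].
#' @param config A [reconstruction_config()] (supplies the underreporting
#'   factor).
#' @return Removals, always `>= landed * underreport_factor`.
#' @export
to_removals <- function(landed, year, schedule = loss_schedule(),
                        config = reconstruction_config()) {
  if (any(landed < 0, na.rm = TRUE)) stop("landed must be >= 0")
  landed * config$underreport_factor / (1 - loss_rate(year, schedule))
}

#' Reconstruct the complete removals series
#'
#' Composition of [fill_missing_years()] and [to_removals()]: the forcing
#' series the population model consumes.
#'
#' @inheritParams fill_missing_years
#' @param schedule A [loss_schedule()].
#' @return A `data.frame` of class `removals_series` with columns
#'   `year, landed, removals, extrapolated`.
#' @export
#' @examples
#' rec <- reported_catch(1960:1969,
#'                       landed = c(132, 132, 440, rep(132, 7)))
#' reconstruct(rec, range = c(1960, 1975))
reconstruct <- function(series, schedule = loss_schedule(),
                        config = reconstruction_config(), range) {
  filled <- fill_missing_years(series, config, range)
  filled$removals <- to_removals(filled$landed, filled$year, schedule, config)
  out <- filled[, c("year", "landed", "removals", "extrapolated")]
  class(out) <- c("removals_series", "data.frame")
  out
}
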