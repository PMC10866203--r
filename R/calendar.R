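#' Wave calendar
#'
#' A wave calendar is the set of labelled, closed date intervals that delimit
#' the pandemic waves used as instruments. Waves must be chronologically
#' ordered and non-overlapping. The derived after-wave indicator is 1 on any
#' day strictly after the end of the first wave that does not fall inside a
#' wave interval; days before the first wave carry all-zero instruments and
#' act as the baseline period.
#'
#' @param waves a named list of length-2 Date (or coercible) vectors,
#'   `list(wave1 = c(start, end), ...)`, in chronological order.
#' @return an object of class `wave_calendar`.
#' @examples
#' cal <- wave_calendar(list(
#'   wave1 = c("2020-01-25", "2020-02-29"),
#'   wave2 = c("2020-03-15", "2020-04-30")
#' ))
#' cal
#' @export
wave_calendar <- function(waves) {
  if (!is.list(waves) || length(waves) == 0L || is.null(names(waves)) ||
      any(!nzchar(names(waves)))) {
    stop("`waves` must be a non-empty named list of date intervals")
  }
  waves <- lapply(waves, function(w) {
    w <- as.Date(w)
    if (length(w) != 2L || anyNA(w)) stop("each wave must be c(start, end)")
    if (w[1L] > w[2L]) stop("wave start must not be after wave end")
    w
  })
  starts <- as.Date(vapply(waves, function(w) as.character(w[1L]), ""))
  ends <- as.Date(vapply(waves, function(w) as.character(w[2L]), ""))
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("waves must be in chronological order")
  }
  if (any(starts[-1L] <= ends[-length(ends)])) {
    stop("wave intervals must not overlap")
  }
  structure(list(waves = waves), class = "wave_calendar")
}

#' @export
print.wave_calendar <- function(x, ...) {
  cat("Wave calendar (", length(x$waves), " waves)\n", sep = "")
  for (nm in names(x$waves)) {
    w <- x$waves[[nm]]
    cat(sprintf("  %-12s %s .. %s (%d days)\n", nm,
                format(w[1L]), format(w[2L]),
                as.integer(w[2L] - w[1L]) + 1L))
  }
  invisible(x)
}

#' Default illustrative wave calendar
#'
#' Four wave intervals over 2020-2021 shaped like Hong Kong's four distinct
#' COVID-19 waves (a short first wave from late January 2020, a spring second
#' wave, a summer third wave, and a long winter fourth wave ending
#' 2021-02-18). These dates are illustrative defaults, not the official
#' government designations: real analyses should supply the official
#' calendar via [wave_calendar()].
#'
#' @return a `wave_calendar` with waves `wave1`..`wave4`.
#' @export
default_wave_calendar <- function() {
  wave_calendar(list(
    wave1 = c("2020-01-25", "2020-02-29"),
    wave2 = c("2020-03-15", "2020-04-30"),
    wave3 = c("2020-07-05", "2020-09-15"),
    wave4 = c("2020-11-15", "2021-02-18")
  ))
}

#' Instrument indicator matrix for a vector of dates
#'
#' Builds the binary instrument columns: `after_wave` plus one column per
#' wave. Wave columns are 1 on days inside the closed wave interval; the
#' after-wave column is 1 on non-wave days strictly after the end of the
#' first wave.
#'
#' @param dates Date vector.
#' @param calendar a [wave_calendar()].
#' @return integer matrix with `length(dates)` rows, columns
#'   `after_wave`, then the wave labels.
#' @export
instrument_matrix <- function(dates, calendar) {
  stopifnot(inherits(calendar, "wave_calendar"))
  dates <- as.Date(dates)
  wv <- calendar$waves
  Z <- matrix(0L, nrow = length(dates), ncol = length(wv) + 1L,
              dimnames = list(NULL, c("after_wave", names(wv))))
  in_any <- rep(FALSE, length(dates))
  for (nm in names(wv)) {
    inside <- dates >= wv[[nm]][1L] & dates <= wv[[nm]][2L]
    Z[, nm] <- as.integer(inside)
    in_any <- in_any | inside
  }
  first_end <- wv[[1L]][2L]
  Z[, "after_wave"] <- as.integer(dates > first_end & !in_any)
  Z
}

#' Seasonal covariates for a vector of dates
#'
#' Year index (first year of the study window is 0), 0-based day-of-year `t`
#' (January 1 is 0), and its square and cube. These four terms enter both
#' regression stages of the 2SLS model as seasonality adjustment.
#'
#' @param dates Date vector.
#' @param year0 integer year mapped to index 0; defaults to the year of the
#'   earliest date.
#' @return numeric matrix with columns `year`, `t`, `t2`, `t3`.
#' @export
seasonal_covariates <- function(dates, year0 = NULL) {
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  if (is.null(year0)) year0 <- min(yr)
  t <- as.numeric(dates - as.Date(paste0(yr, "-01-01")))
  cbind(year = yr - year0, t = t, t2 = t^2, t3 = t^3)
}

# days in the closed interval, whole-day calendar arithmetic
interval_days <- function(interval) {
  interval <- as.Date(interval)
  as.integer(interval[2L] - interval[1L]) + 1L
}
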