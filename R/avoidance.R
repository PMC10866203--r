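#' Period change arithmetic
#'
#' The change computation every table in the package funnels through:
#' absolute change `current - baseline` and percent change
#' `100 * (current - baseline) / baseline`. Percent change is `NA` (flagged
#' via attribute `zero_baseline`) when the baseline is zero.
#'
#' @param baseline baseline-period count (e.g. a 2016-2019 same-period
#'   average).
#' @param current current-period count.
#' @param label optional row label.
#' @return data.frame row: `label`, `baseline`, `current`, `change`,
#'   `pct_change`.
#' @examples
#' period_change(2142609, 1594493)   # -548116 visits, -25.6%
#' @export
period_change <- function(baseline, current, label = NA_character_) {
  out <- data.frame(label = label, baseline = baseline, current = current,
                    change = current - baseline,
                    pct_change = ifelse(baseline != 0,
                                        100 * (current - baseline) / baseline,
                                        NA_real_),
                    stringsAsFactors = FALSE)
  if (any(baseline == 0)) attr(out, "zero_baseline") <- TRUE
  out
}

# map a set of days onto the same calendar (month-day) days of another year;
# Feb 29 is dropped when the target year has none
same_period_days <- function(days, year) {
  md <- format(days, "%m-%d")
  md <- md[md != "02-29" | is_leap(year)]
  as.Date(paste0(year, "-", md))
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

# resolve a period argument to a vector of days: either c(start, end) or an
# explicit day set
period_days <- function(period) {
  period <- as.Date(period)
  if (length(period) == 2L && period[1L] <= period[2L] &&
      is.null(attr(period, "dayset"))) {
    seq(period[1L], period[2L], by = "day")
  } else period
}

count_in_days <- function(records, days, count = c("visits", "deaths28")) {
  count <- match.arg(count)
  if (count == "visits") {
    sum(records$visit_date %in% days)
  } else {
    # distinct patients whose last visit lies in the day set and who died
    # within 28 days of it
    dec_ids <- unique(records$patient_id[!is.na(records$death_date)])
    dec <- records[records$patient_id %in% dec_ids, , drop = FALSE]
    if (nrow(dec) == 0L) return(0L)
    dt <- data.table::as.data.table(dec)
    last <- dt[, list(last_visit = max(visit_date),
                      death_date = death_date[!is.na(death_date)][1L]),
               by = "patient_id"]
    sum(last$last_visit %in% days &
          flag_28day_death(last$last_visit, last$death_date))
  }
}

#' Seasonally adjusted period change
#'
#' Counts events (visits, or 28-day deaths tallied by last visit date) in a
#' period and compares them with the average count over the same
#' calendar-day window in each baseline year — the "same-period 2016-2019
#' average" adjustment. February 29 is excluded when a baseline year lacks
#' it.
#'
#' @param records visit record data.frame (COVID-positive records already
#'   excluded).
#' @param period either `c(start, end)` dates or an explicit Date vector of
#'   days (e.g. the non-contiguous wave days of a year).
#' @param baseline_years integer vector of baseline years (default
#'   2016:2019).
#' @param count `"visits"` or `"deaths28"`.
#' @param age_group,sex,ltc,doa_dba optional filters; `ltc`/`doa_dba`
#'   take 0/1.
#' @param label optional row label.
#' @return a [period_change()] row.
#' @export
seasonally_adjusted_change <- function(records, period,
                                       baseline_years = 2016:2019,
                                       count = c("visits", "deaths28"),
                                       age_group = NULL, sex = NULL,
                                       ltc = NULL, doa_dba = NULL,
                                       label = NA_character_) {
  count <- match.arg(count)
  rec <- records
  if (!is.null(age_group)) {
    rec <- rec[as.character(edexcess::age_group(rec$age)) %in% age_group, ]
  }
  if (!is.null(sex)) rec <- rec[rec$sex %in% sex, ]
  if (!is.null(ltc)) rec <- rec[rec$ltc %in% ltc, ]
  if (!is.null(doa_dba)) rec <- rec[rec$doa_dba %in% doa_dba, ]

  days <- period_days(period)
  if (length(days) == 0L) stop("empty period")
  if (nrow(rec)) {
    data_range <- range(rec$visit_date)
    if (min(days) > data_range[2L] || max(days) < data_range[1L]) {
      stop("period lies outside the data")
    }
  }
  current <- count_in_days(rec, days, count)
  base_counts <- vapply(baseline_years, function(y) {
    as.numeric(count_in_days(rec, same_period_days(days, y), count))
  }, numeric(1))
  period_change(mean(base_counts), current, label = label)
}

#' DOA/DBA death breakdown among older people
#'
#' Tabulates 28-day deaths among patients aged >= 65 by DOA/DBA status and
#' wave/non-wave period for each pandemic year, against the same-period
#' baseline average — the wave-resolved view of where the excess deaths
#' concentrate. A decedent is classed DOA/DBA when any visit carries the
#' flag.
#'
#' @param records visit record data.frame.
#' @param calendar a [wave_calendar()].
#' @param years pandemic years to evaluate (default `c(2020, 2021)`).
#' @param baseline_years baseline years (default 2016:2019).
#' @param min_age age threshold (default 65).
#' @return data.frame, one row per year x DOA status x wave/nonwave:
#'   baseline deaths, current deaths, absolute and percent change.
#' @export
doa_breakdown <- function(records, calendar, years = c(2020, 2021),
                          baseline_years = 2016:2019, min_age = 65) {
  stopifnot(inherits(calendar, "wave_calendar"))
  rec <- records[records$age >= min_age, , drop = FALSE]
  rows <- list()
  for (y in years) {
    periods <- year_wave_periods(calendar, y)
    for (status in c(0L, 1L)) {
      for (pn in names(periods)) {
        ch <- seasonally_adjusted_change(
          rec, periods[[pn]], baseline_years = baseline_years,
          count = "deaths28", doa_dba = status,
          label = sprintf("%d %s, %s", y,
                          if (status == 1L) "DOA/DBA" else "non-DOA/DBA", pn))
        ch$year <- y
        ch$doa_dba <- status
        ch$period <- pn
        rows[[length(rows) + 1L]] <- ch
      }
    }
  }
  do.call(rbind, rows)
}

#' Individual incidence rate
#'
#' A patient's ED visit rate over a period: visits in the period divided by
#' the period length in days.
#'
#' @param visit_dates the patient's visit dates.
#' @param period `c(start, end)` Date interval (closed).
#' @return visits per day.
#' @export
incidence_rate <- function(visit_dates, period) {
  period <- as.Date(period)
  stopifnot(length(period) == 2L, period[1L] <= period[2L])
  visit_dates <- as.Date(visit_dates)
  n <- sum(visit_dates >= period[1L] & visit_dates <= period[2L])
  n / interval_days(period)
}

#' Group specification for the incidence-rate comparison
#'
#' Date windows defining one DOA/DBA decedent group: the window in which the
#' qualifying DOA/DBA visit occurred, and the control and treatment periods
#' whose individual visit rates are compared. The defaults of
#' [covid_group_spec()] and [precovid_group_spec()] are the study's COVID
#' and pre-COVID group definitions.
#'
#' @param doa_window,control,treatment `c(start, end)` Date intervals;
#'   control and treatment must not overlap.
#' @param label group label.
#' @return a `group_spec` list.
#' @export
group_spec <- function(doa_window, control, treatment, label = "group") {
  doa_window <- as.Date(doa_window); control <- as.Date(control)
  treatment <- as.Date(treatment)
  stopifnot(length(doa_window) == 2L, length(control) == 2L,
            length(treatment) == 2L)
  if (max(control[1L], treatment[1L]) <= min(control[2L], treatment[2L])) {
    stop("control and treatment periods must not overlap")
  }
  structure(list(doa_window = doa_window, control = control,
                 treatment = treatment, label = label),
            class = "group_spec")
}

#' @rdname group_spec
#' @export
covid_group_spec <- function() {
  group_spec(doa_window = c("2020-07-01", "2021-07-01"),
             control = c("2019-01-01", "2020-01-24"),
             treatment = c("2020-01-25", "2020-06-30"),
             label = "COVID")
}

#' @rdname group_spec
#' @export
precovid_group_spec <- function() {
  group_spec(doa_window = c("2018-07-01", "2019-07-01"),
             control = c("2017-01-01", "2017-06-30"),
             treatment = c("2018-01-01", "2018-06-30"),
             label = "pre-COVID")
}

#' Categorize DOA/DBA decedents by incidence-rate change
#'
#' Identifies patients aged >= `min_age` with a DOA/DBA visit inside the
#' group's window, keeps those with at least two visits in the control
#' period (the eligibility rule), and assigns each to exactly one category:
#' `increase` when the treatment-period rate exceeds the control rate,
#' `no_visits` when there are no treatment-period visits, `reduction`
#' otherwise (ties with visits land in `reduction`). The three categories
#' partition the eligible decedents.
#'
#' @param records visit record data.frame.
#' @param spec a [group_spec()].
#' @param min_age age threshold (default 65).
#' @return list with `label`, `eligible` (count), `counts` (named:
#'   increase, no_visits, reduction), and the per-patient table `patients`
#'   (`patient_id`, control/treatment rates, `category`).
#' @export
categorize_decedents <- function(records, spec, min_age = 65) {
  stopifnot(inherits(spec, "group_spec"))
  doa_rec <- records[records$doa_dba == 1L & records$age >= min_age &
                       records$visit_date >= spec$doa_window[1L] &
                       records$visit_date <= spec$doa_window[2L], ,
                     drop = FALSE]
  ids <- unique(doa_rec$patient_id)
  all_visits <- records[records$patient_id %in% ids, , drop = FALSE]
  split_dates <- split(all_visits$visit_date, all_visits$patient_id)

  rows <- lapply(ids, function(id) {
    vd <- split_dates[[id]]
    ctrl_n <- sum(vd >= spec$control[1L] & vd <= spec$control[2L])
    if (ctrl_n < 2L) return(NULL)
    cr <- ctrl_n / interval_days(spec$control)
    tn <- sum(vd >= spec$treatment[1L] & vd <= spec$treatment[2L])
    tr <- tn / interval_days(spec$treatment)
    category <- if (tn == 0L) "no_visits" else if (tr > cr) "increase"
                else "reduction"
    data.frame(patient_id = id, control_rate = cr, treatment_rate = tr,
               category = category, stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, rows)
  if (is.null(patients)) {
    patients <- data.frame(patient_id = character(0),
                           control_rate = numeric(0),
                           treatment_rate = numeric(0),
                           category = character(0))
  }
  counts <- vapply(c("increase", "no_visits", "reduction"),
                   function(k) sum(patients$category == k), integer(1))
  list(label = spec$label, eligible = nrow(patients), counts = counts,
       patients = patients)
}

#' Two-sample (two-proportion) z test
#'
#' Pooled-variance two-proportion z:
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with
#' `p = (x1 + x2)/(n1 + n2)`, two-sided p-value. When the pooled proportion
#' is 0 or 1 the statistic is undefined and both values are `NA` with a
#' `degenerate` flag. An unpooled variant is available.
#'
#' @param x1,n1 count and total of group 1.
#' @param x2,n2 count and total of group 2.
#' @param pooled use the pooled variance (default TRUE).
#' @return list with `z`, `p`, `p1`, `p2`, and `degenerate`.
#' @examples
#' two_sample_z(427, 928, 201, 658)$p   # far below .001
#' @export
two_sample_z <- function(x1, n1, x2, n2, pooled = TRUE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  if (pooled) {
    p <- (x1 + x2) / (n1 + n2)
    if (p == 0 || p == 1) {
      return(list(z = NA_real_, p = NA_real_, p1 = p1, p2 = p2,
                  degenerate = TRUE))
    }
    sd <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  } else {
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
    if (v == 0) {
      return(list(z = NA_real_, p = NA_real_, p1 = p1, p2 = p2,
                  degenerate = TRUE))
    }
    sd <- sqrt(v)
  }
  z <- (p1 - p2) / sd
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Incidence-rate comparison between two decedent groups
#'
#' Runs [categorize_decedents()] for two group specifications and compares
#' the category counts with per-category two-proportion z tests (each
#' category's count over the group's eligible total).
#'
#' @param records visit record data.frame.
#' @param spec1,spec2 [group_spec()]s (e.g. [covid_group_spec()] and
#'   [precovid_group_spec()]).
#' @param min_age age threshold.
#' @param pooled passed to [two_sample_z()].
#' @return object of class `incidence_comparison`: the two group results
#'   and a `table` with per-category counts, z and p.
#' @export
compare_incidence_rates <- function(records, spec1 = covid_group_spec(),
                                    spec2 = precovid_group_spec(),
                                    min_age = 65, pooled = TRUE) {
  g1 <- categorize_decedents(records, spec1, min_age = min_age)
  g2 <- categorize_decedents(records, spec2, min_age = min_age)
  cats <- c("increase", "no_visits", "reduction")
  tab <- do.call(rbind, lapply(cats, function(k) {
    zt <- if (g1$eligible > 0 && g2$eligible > 0) {
      two_sample_z(g1$counts[[k]], g1$eligible, g2$counts[[k]], g2$eligible,
                   pooled = pooled)
    } else list(z = NA_real_, p = NA_real_)
    data.frame(category = k, n1 = g1$counts[[k]], total1 = g1$eligible,
               n2 = g2$counts[[k]], total2 = g2$eligible,
               z = zt$z, p = zt$p, stringsAsFactors = FALSE)
  }))
  structure(list(group1 = g1, group2 = g2, table = tab),
            class = "incidence_comparison")
}

#' @export
print.incidence_comparison <- function(x, ...) {
  cat("Incidence-rate comparison: ", x$group1$label, " (n=",
      x$group1$eligible, ") vs ", x$group2$label, " (n=",
      x$group2$eligible, ")\n", sep = "")
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
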