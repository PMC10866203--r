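#' Read / write visit records
#'
#' Visit-record CSV dialect: columns `patient_id`, `visit_date` (ISO-8601),
#' `age`, `sex` (M/F), `ltc` (0/1), `doa_dba` (0/1), `covid_pcr` (0/1),
#' `icd9_codes` (semicolon-joined), `death_date` (ISO-8601 or empty).
#'
#' @param path file path.
#' @return `read_visit_records`: data.frame with `visit_date`/`death_date`
#'   as `Date`.
#' @export
read_visit_records <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("patient_id", "sex", "icd9_codes"),
    integer = c("age", "ltc", "doa_dba", "covid_pcr"),
    Date = c("visit_date", "death_date")))
  rec <- as.data.frame(dt)
  validate_visit_records(rec)
  rec
}

#' @param records visit record data.frame.
#' @rdname read_visit_records
#' @export
write_visit_records <- function(records, path) {
  validate_visit_records(records)
  data.table::fwrite(records, path, dateTimeAs = "ISO")
  invisible(path)
}

validate_visit_records <- function(rec) {
  need <- c("patient_id", "visit_date", "age", "sex", "ltc", "doa_dba",
            "covid_pcr", "icd9_codes", "death_date")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(rec$age < 0, na.rm = TRUE)) stop("negative ages in records")
  bad <- !is.na(rec$death_date) & rec$death_date < rec$visit_date
  if (any(bad)) {
    stop(sum(bad), " record(s) have death_date before visit_date")
  }
  invisible(rec)
}

#' Exclude PCR-positive visit records
#'
#' Removes visits with a positive COVID-19 PCR result from the analysis
#' population, reporting the number removed via a message and the
#' `n_excluded` attribute.
#'
#' @param records visit record data.frame.
#' @param quiet suppress the message.
#' @return the records with `covid_pcr == 1` rows removed.
#' @export
exclude_covid_positive <- function(records, quiet = FALSE) {
  drop <- records$covid_pcr == 1L
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet) message("excluded ", sum(drop), " COVID-19 PCR-positive visits")
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' 28-day mortality flag for a visit
#'
#' A visit is followed by a 28-day death when a death date exists and falls
#' 0 to 28 whole days (inclusive on both ends) after the visit date. Death
#' on the visit day itself counts — DOA/DBA cases require it. Vectorized.
#'
#' @param visit_date,death_date Date vectors (death may be `NA`).
#' @return logical vector.
#' @export
flag_28day_death <- function(visit_date, death_date) {
  visit_date <- as.Date(visit_date)
  death_date <- as.Date(death_date)
  diff <- as.numeric(death_date - visit_date)
  if (any(diff < 0, na.rm = TRUE)) {
    stop("death_date before visit_date")
  }
  !is.na(diff) & diff <= 28
}

#' Tally daily visits and 28-day deaths for one stratum
#'
#' Builds the daily series the causal model consumes: `visits[t]` counts the
#' stratum's visits on day `t`; `deaths28[t]` counts distinct patients whose
#' *last* visit in the records was on day `t` and who died within 28 days of
#' it. A patient with several visits contributes every visit to the visit
#' tally but at most one 28-day death, attached to the last visit date, so
#' mortality is never double counted. Days without events are present with
#' zeros.
#'
#' @param records visit record data.frame (COVID-positive visits already
#'   excluded; records of one stratum, or pass `age_group`/`sex` to filter).
#' @param window length-2 Date vector, the study window; records outside it
#'   are an error.
#' @param age_group,sex optional stratum filters.
#' @return data.frame `date`, `visits`, `deaths28` over every day of the
#'   window.
#' @export
tally_daily <- function(records, window, age_group = NULL, sex = NULL) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  rec <- records
  if (!is.null(age_group)) {
    rec <- rec[as.character(edexcess::age_group(rec$age)) %in% age_group, ]
  }
  if (!is.null(sex)) rec <- rec[rec$sex %in% sex, ]

  out_of_window <- rec$visit_date < window[1L] | rec$visit_date > window[2L]
  if (any(out_of_window)) {
    stop("records outside the study window: ",
         paste(utils::head(rec$patient_id[out_of_window], 5L),
               collapse = ", "),
         if (sum(out_of_window) > 5L) " ..." else "")
  }

  days <- seq(window[1L], window[2L], by = "day")
  visits <- tabulate(as.integer(rec$visit_date - window[1L]) + 1L,
                     nbins = length(days))

  deaths28 <- integer(length(days))
  dec_ids <- unique(rec$patient_id[!is.na(rec$death_date)])
  dec <- rec[rec$patient_id %in% dec_ids, , drop = FALSE]
  if (nrow(dec)) {
    dt <- data.table::as.data.table(dec)
    last <- dt[, list(last_visit = max(visit_date),
                      death_date = death_date[!is.na(death_date)][1L]),
               by = "patient_id"]
    counted <- last[flag_28day_death(last$last_visit, last$death_date)]
    if (nrow(counted)) {
      deaths28 <- tabulate(
        as.integer(counted$last_visit - window[1L]) + 1L,
        nbins = length(days))
    }
  }
  data.frame(date = days, visits = as.integer(visits),
             deaths28 = as.integer(deaths28))
}

#' Tally all strata
#'
#' Applies [tally_daily()] to every age-group x sex stratum present in the
#' stratum table.
#'
#' @param records visit record data.frame.
#' @param window length-2 Date study window.
#' @return named list of daily series, labels `"age_group/sex"`.
#' @export
tally_all_strata <- function(records, window) {
  grid <- expand.grid(age_group = age_group_levels(), sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  ag <- as.character(age_group(records$age))
  out <- vector("list", nrow(grid))
  names(out) <- stratum_label(grid$age_group, grid$sex)
  for (i in seq_len(nrow(grid))) {
    sub <- records[ag == grid$age_group[i] & records$sex == grid$sex[i], ,
                   drop = FALSE]
    out[[i]] <- tally_daily(sub, window)
  }
  out
}

#' Stratum exclusion rule
#'
#' Drops strata whose mean daily 28-day mortality over the full window is
#' at or below the threshold (default 1, inclusive): such series are too
#' sparse for stable instrumental-variable estimation.
#'
#' @param series named list of daily series (as from [tally_all_strata()]).
#' @param threshold mean daily deaths at or below which a stratum is
#'   dropped.
#' @param quiet suppress the message listing dropped strata.
#' @return the retained subset of `series`, with attribute `dropped`.
#' @export
apply_stratum_exclusion <- function(series, threshold = 1, quiet = FALSE) {
  mean_deaths <- vapply(series, function(s) mean(s$deaths28), numeric(1))
  keep <- mean_deaths > threshold
  if (!quiet && any(!keep)) {
    message("excluded strata (mean daily 28-day deaths <= ", threshold,
            "): ", paste(names(series)[!keep], collapse = ", "))
  }
  out <- series[keep]
  attr(out, "dropped") <- names(series)[!keep]
  out
}

#' Write a daily series CSV
#'
#' @param series data.frame `date`, `visits`, `deaths28`.
#' @param path file path.
#' @export
write_daily_series <- function(series, path) {
  data.table::fwrite(series, path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_daily_series
#' @export
read_daily_series <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    Date = "date", integer = c("visits", "deaths28"))))
}
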