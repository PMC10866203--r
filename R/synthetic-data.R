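#' Generate daily visit and 28-day death counts
#'
#' Simulates, for every stratum in the configuration, the structural model
#' behind the instrumental-variable design: visits respond to wave
#' indicators on top of a smooth seasonal and yearly baseline, and 28-day
#' deaths respond to the realized visit count through the stratum causal
#' coefficient `theta1`, at the configured lag, with noise correlated with
#' the visit noise (the confounder). Gaussian noise is applied on the linear
#' scale, then counts are rounded and clipped at zero; daily deaths are
#' additionally capped at the day's visits because a 28-day death is tallied
#' on its decedent's last visit day.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   * `series`: named list (one per stratum, label `"age/sex"`) of
#'     data.frames `date`, `visits`, `deaths28`;
#'   * `truth`: a `ground_truth` data.frame with per-stratum `theta1_true`,
#'     expected total `visit_reduction` over all instrument periods, and
#'     `implied_excess = -theta1_true * visit_reduction`;
#'   * `config`: the input configuration.
#' @details Configurations whose expected daily visit count is negative on
#'   more than 1% of stratum-days are rejected: wave effects that large
#'   relative to the baseline rate signal an implausible parameterization
#'   that the round-and-clip noise model would distort.
#' @examples
#' out <- generate_daily_counts(single_stratum_config(seed = 7))
#' head(out$series[[1]])
#' out$truth
#' @export
generate_daily_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_daily_counts_impl(config))
}

generate_daily_counts_impl <- function(config) {
  dates <- seq(config$study_start, config$study_end, by = "day")
  n <- length(dates)
  Z <- instrument_matrix(dates, config$calendar)
  beta <- c(config$beta_after, config$beta_wave)  # after_wave first, as in Z
  wave_term_agg <- as.numeric(Z %*% beta)         # aggregate visits/day
  yr_idx <- as.integer(format(dates, "%Y")) -
    as.integer(format(config$study_start, "%Y"))
  doy <- as.numeric(dates - as.Date(paste0(format(dates, "%Y"), "-01-01")))
  season_agg <- config$season_amp * sin(2 * pi * doy / 365.25)

  st <- config$strata
  share <- st$visit_rate / sum(st$visit_rate)
  lag <- config$lag
  rho <- config$confound_rho

  series <- vector("list", nrow(st))
  names(series) <- stratum_label(st$age_group, st$sex)
  reduction <- numeric(nrow(st))

  # implausibility check on expected counts, across all strata
  neg_frac <- 0
  for (s in seq_len(nrow(st))) {
    mu <- st$visit_rate[s] * (1 + config$year_trend * yr_idx) +
      share[s] * (season_agg + wave_term_agg)
    neg_frac <- neg_frac + mean(mu < 0) / nrow(st)
  }
  if (neg_frac > 0.01) {
    stop("expected visit counts negative on ", round(100 * neg_frac, 1),
         "% of stratum-days; implausible configuration")
  }

  for (s in seq_len(nrow(st))) {
    base_A <- st$visit_rate[s] * (1 + config$year_trend * yr_idx) +
      share[s] * season_agg
    mu_A <- base_A + share[s] * wave_term_agg
    sd_u <- sqrt(pmax(mu_A, 1))
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    u <- sd_u * z1
    A <- pmax(0, round(mu_A + u))

    mu0_D <- st$death_rate[s] * (1 + config$year_trend * yr_idx)
    sd_v <- sqrt(pmax(mu0_D, 0.25))
    v <- sd_v * (rho * z1 + sqrt(1 - rho^2) * z2)

    # D[t + lag] responds to the realized visits A[t]
    D_struct <- mu0_D + v
    if (lag == 0L) {
      D_struct <- D_struct + st$theta1[s] * (A - base_A)
    } else {
      idx <- seq_len(n - lag)
      D_struct[idx + lag] <- D_struct[idx + lag] +
        st$theta1[s] * (A[idx] - base_A[idx])
    }
    D <- pmax(0, pmin(round(D_struct), A))

    series[[s]] <- data.frame(date = dates, visits = as.integer(A),
                              deaths28 = as.integer(D))
    reduction[s] <- -share[s] * sum(wave_term_agg)
  }

  truth <- data.frame(
    age_group = st$age_group, sex = st$sex,
    theta1_true = st$theta1,
    visit_reduction = reduction,
    implied_excess = -st$theta1 * reduction,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("ground_truth", "data.frame")
  attr(truth, "beta_wave") <- config$beta_wave
  attr(truth, "beta_after") <- config$beta_after
  list(series = series, truth = truth, config = config)
}

#' Generate visit-level records from daily count series
#'
#' Expands the per-stratum daily count series into one row per ED visit with
#' the registry-like columns the cohort ETL consumes: patient identifier,
#' visit date, age, sex, long-term-care and death-on-arrival flags, a PCR
#' positivity flag, semicolon-joined ICD-9-CM diagnosis codes, and a death
#' date for 28-day decedents.
#'
#' Per stratum-day, exactly `visits[t]` non-COVID records are emitted; a
#' configurable fraction are return visits by previously seen patients.
#' `deaths28[t]` distinct patients among that day's visitors are marked as
#' decedents, never visit again, and receive a death date 0-28 days after
#' the visit (0 for death-on-arrival cases), so tallying records by last
#' visit date reproduces the input series exactly. `covid_positive_count`
#' additional PCR-positive records are emitted on pandemic days (2020
#' onward, or the whole window when it ends earlier) on top of the series
#' counts; the ETL's exclusion step removes them again.
#'
#' @param config the [sim_config()] used to generate `counts`.
#' @param counts result of [generate_daily_counts()] (or its `series`
#'   element).
#' @return data.frame of visit records, ordered by visit date then patient,
#'   with columns `patient_id`, `visit_date`, `age`, `sex`, `ltc`,
#'   `doa_dba`, `covid_pcr`, `icd9_codes`, `death_date`.
#' @export
generate_visit_records <- function(config, counts) {
  stopifnot(inherits(config, "sim_config"))
  series <- if (!is.null(counts$series)) counts$series else counts
  with_seed(config$seed + 1L, generate_visit_records_impl(config, series))
}

generate_visit_records_impl <- function(config, series) {
  st <- config$strata
  out <- vector("list", nrow(st))
  code_pool <- deyo_code_samples()
  prev <- config$comorbidity_prevalence

  for (s in seq_len(nrow(st))) {
    lab <- stratum_label(st$age_group[s], st$sex[s])
    ser <- series[[lab]]
    if (is.null(ser)) stop("missing series for stratum ", lab)
    is_old <- st$age_group[s] == ">=65"
    ages_rng <- switch(st$age_group[s],
      "0-17" = c(0L, 17L), "18-34" = c(18L, 34L), "35-44" = c(35L, 44L),
      "45-54" = c(45L, 54L), "55-64" = c(55L, 64L), c(65L, 95L))

    nrec_total <- sum(ser$visits)
    pid <- integer(nrec_total)      # per-record patient index
    day_of <- integer(nrec_total)   # row index into ser
    pos <- 0L

    # patient registry grows as patients appear
    n_pat <- 0L
    pat_age <- integer(nrec_total)
    pat_ltc <- logical(nrec_total)
    dd_day <- rep(NA_integer_, nrec_total)
    dd_off <- rep(NA_integer_, nrec_total)
    dd_doa <- rep(FALSE, nrec_total)

    pool <- integer(0)
    pool_cap <- 3000L

    for (t in seq_len(nrow(ser))) {
      nt <- ser$visits[t]
      if (nt == 0L) {
        if (ser$deaths28[t] > 0L) {
          stop("deaths28 > 0 on a day with no visits (stratum ", lab, ")")
        }
        next
      }
      r <- if (length(pool)) min(stats::rbinom(1L, nt, config$repeat_fraction),
                                 nt) else 0L
      reused <- if (r > 0L) sample(pool, r, replace = TRUE) else integer(0)
      n_new <- nt - r
      new_idx <- if (n_new > 0L) n_pat + seq_len(n_new) else integer(0)
      if (n_new > 0L) {
        pat_age[new_idx] <- sample(ages_rng[1L]:ages_rng[2L], n_new,
                                   replace = TRUE)
        pat_ltc[new_idx] <- if (is_old) {
          stats::runif(n_new) < config$ltc_fraction
        } else FALSE
        n_pat <- n_pat + n_new
      }
      today <- c(reused, new_idx)
      pid[pos + seq_len(nt)] <- today
      day_of[pos + seq_len(nt)] <- t
      pos <- pos + nt

      dt <- ser$deaths28[t]
      if (dt > 0L) {
        uniq <- unique(today)
        if (dt > length(uniq)) {
          stop("more 28-day deaths than distinct visitors on ",
               format(ser$date[t]), " (stratum ", lab, ")")
        }
        dec <- if (length(uniq) == 1L) uniq else sample(uniq, dt)
        is_doa <- stats::runif(dt) < config$doa_fraction
        off <- ifelse(is_doa, 0L, sample(0:28, dt, replace = TRUE))
        dd_day[dec] <- t
        dd_off[dec] <- off
        dd_doa[dec] <- is_doa
        pool <- setdiff(pool, dec)
        new_idx <- setdiff(new_idx, dec)  # decedents never visit again
      }
      pool <- c(pool, new_idx)
      if (length(pool) > pool_cap) {
        pool <- pool[(length(pool) - pool_cap + 1L):length(pool)]
      }
    }

    rec <- data.frame(
      patient_id = sprintf("S%02d-%07d", s, pid),
      visit_date = ser$date[day_of],
      age = pat_age[pid],
      sex = st$sex[s],
      ltc = as.integer(pat_ltc[pid]),
      stringsAsFactors = FALSE
    )
    dday <- dd_day[pid]
    rec$death_date <- as.Date(ifelse(is.na(dday), NA,
                                     ser$date[dday] + dd_off[pid]),
                              origin = "1970-01-01")
    # DOA/DBA is flagged on the decedent's final-day visit(s)
    rec$doa_dba <- as.integer(!is.na(dday) & dd_doa[pid] & day_of == dday)
    rec$covid_pcr <- 0L
    rec$icd9_codes <- draw_icd9_codes(nrow(rec), prev, code_pool)
    out[[s]] <- rec
  }

  rec <- do.call(rbind, out)

  if (config$covid_positive_count > 0L) {
    rec <- rbind(rec, covid_positive_records(config))
  }

  rec <- rec[order(rec$visit_date, rec$patient_id), ]
  rownames(rec) <- NULL
  rec[, c("patient_id", "visit_date", "age", "sex", "ltc", "doa_dba",
          "covid_pcr", "icd9_codes", "death_date")]
}

# semicolon-joined ICD-9-CM code strings drawn per Deyo-category prevalence
draw_icd9_codes <- function(n, prevalence, code_pool) {
  if (n == 0L || length(prevalence) == 0L) return(character(n))
  cols <- lapply(names(prevalence), function(k) {
    hit <- stats::runif(n) < prevalence[[k]]
    out <- character(n)
    nh <- sum(hit)
    if (nh > 0L) out[hit] <- sample(code_pool[[k]], nh, replace = TRUE)
    out
  })
  joined <- do.call(paste, c(cols, sep = ";"))
  joined <- gsub(";{2,}", ";", joined)
  gsub("^;|;$", "", joined)
}

covid_positive_records <- function(config) {
  k <- config$covid_positive_count
  pand_start <- max(config$study_start, as.Date("2020-01-01"))
  if (pand_start > config$study_end) pand_start <- config$study_start
  days <- seq(pand_start, config$study_end, by = "day")
  st <- config$strata
  srow <- sample(nrow(st), k, replace = TRUE,
                 prob = st$visit_rate / sum(st$visit_rate))
  ages_lo <- c("0-17" = 0L, "18-34" = 18L, "35-44" = 35L, "45-54" = 45L,
               "55-64" = 55L, ">=65" = 65L)
  ages_hi <- c("0-17" = 17L, "18-34" = 34L, "35-44" = 44L, "45-54" = 54L,
               "55-64" = 64L, ">=65" = 95L)
  ag <- st$age_group[srow]
  data.frame(
    patient_id = sprintf("C-%07d", seq_len(k)),
    visit_date = sample(days, k, replace = TRUE),
    age = ages_lo[ag] +
      floor(stats::runif(k) * (ages_hi[ag] - ages_lo[ag] + 1L)),
    sex = st$sex[srow],
    ltc = 0L,
    death_date = as.Date(NA),
    doa_dba = 0L,
    covid_pcr = 1L,
    icd9_codes = "",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Simulation ground truth\n")
  cat(sprintf("  aggregate wave effects: %s; after=%g (visits/day)\n",
              paste(sprintf("%s=%g", names(attr(x, "beta_wave")),
                            attr(x, "beta_wave")), collapse = ", "),
              attr(x, "beta_after")))
  print.data.frame(x, ...)
  cat(sprintf("  implied total excess deaths: %.1f\n",
              sum(x$implied_excess)))
  invisible(x)
}
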