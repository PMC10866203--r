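#' Simulation configuration
#'
#' Defines the data-generating conditions for the synthetic ED cohort: the
#' study window, the wave calendar, per-stratum baseline daily visit and
#' 28-day death rates, aggregate wave effects on attendance, the stratum
#' causal coefficient linking deaths to visits, and the confounding strength
#' between visit and death noise.
#'
#' The generator simulates the structural model the 2SLS estimator assumes:
#' daily visits \eqn{A_t = \mu_A(t) + \sum_k \beta_k Z_{kt} + u_t} and
#' daily 28-day deaths \eqn{D_{t+i} = \mu_D(t) + \theta_1 (A_t - E[A_t | no
#' wave]) + v_t}, with \eqn{corr(u, v) = \rho}. Nonzero \eqn{\rho} makes the
#' naive OLS regression of deaths on visits biased while the wave-instrument
#' estimator remains consistent for \eqn{\theta_1}.
#'
#' Wave effects `beta_wave` and the after-wave effect `beta_after` are
#' expressed at the aggregate (all-strata) level in visits/day and
#' apportioned to strata proportionally to their baseline visit-rate share,
#' so a single-stratum configuration receives the full effect.
#'
#' @param seed integer RNG seed.
#' @param study_start,study_end study window (Date or coercible).
#' @param calendar a [wave_calendar()]; intervals must lie inside the window.
#' @param strata data.frame with columns `age_group`, `sex`, `visit_rate`
#'   (baseline visits/day), `death_rate` (baseline 28-day deaths/day) and
#'   `theta1` (causal deaths-per-visit coefficient).
#' @param beta_wave named numeric, one entry per calendar wave, aggregate
#'   visit change in visits/day (<= 0 for reductions).
#' @param beta_after aggregate after-wave visit change, visits/day (<= 0).
#' @param confound_rho correlation in (-1, 1) between visit and death noise.
#' @param season_amp aggregate seasonal amplitude, visits/day.
#' @param year_trend multiplicative yearly drift in baseline rates
#'   (0.005 = +0.5%/year).
#' @param lag days between a visit change and the death response (0-14).
#' @param ltc_fraction probability that a patient aged >= 65 is a long-term
#'   care home resident.
#' @param doa_fraction probability that a simulated decedent is a death on
#'   arrival / death before arrival (death on the day of the last visit).
#' @param repeat_fraction probability that a visit is a return visit by an
#'   already-seen patient.
#' @param covid_positive_count number of additional PCR-positive visit
#'   records emitted on pandemic days (excluded again by the ETL).
#' @param comorbidity_prevalence named numeric in `[0, 1]`: per-visit
#'   probability of carrying a diagnosis from each Deyo category (names must
#'   be Deyo category keys, see [deyo_categories()]).
#' @return an object of class `sim_config`.
#' @seealso [default_sim_config()], [single_stratum_config()],
#'   [generate_daily_counts()], [generate_visit_records()]
#' @export
sim_config <- function(seed = 1L,
                       study_start = "2016-01-01",
                       study_end = "2021-12-31",
                       calendar = default_wave_calendar(),
                       strata = default_strata(),
                       beta_wave = c(wave1 = -1500, wave2 = -1300,
                                     wave3 = -1100, wave4 = -1300),
                       beta_after = -500,
                       confound_rho = 0.5,
                       season_amp = 150,
                       year_trend = 0.005,
                       lag = 0L,
                       ltc_fraction = 0.15,
                       doa_fraction = 0.15,
                       repeat_fraction = 0.2,
                       covid_positive_count = 0L,
                       comorbidity_prevalence = default_comorbidity_prevalence()) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (study_start >= study_end) stop("study_start must precede study_end")
  stopifnot(inherits(calendar, "wave_calendar"))
  for (w in calendar$waves) {
    if (w[1L] < study_start || w[2L] > study_end) {
      stop("wave intervals must lie inside the study window")
    }
  }
  req <- c("age_group", "sex", "visit_rate", "death_rate", "theta1")
  if (!is.data.frame(strata) || !all(req %in% names(strata))) {
    stop("`strata` needs columns ", paste(req, collapse = ", "))
  }
  if (any(strata$visit_rate < 0) || any(strata$death_rate < 0)) {
    stop("baseline rates must be non-negative")
  }
  if (!all(strata$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (anyDuplicated(paste(strata$age_group, strata$sex))) {
    stop("duplicate strata")
  }
  if (is.null(names(beta_wave)) ||
      !setequal(names(beta_wave), names(calendar$waves))) {
    stop("beta_wave must be named after the calendar waves")
  }
  beta_wave <- beta_wave[names(calendar$waves)]
  if (any(beta_wave > 0) || beta_after > 0) {
    stop("wave effects must be <= 0 (reductions)")
  }
  if (abs(confound_rho) >= 1) stop("confound_rho must lie in (-1, 1)")
  lag <- as.integer(lag)
  if (lag < 0L || lag > 14L) stop("lag must be in 0..14")
  probs <- c(ltc_fraction, doa_fraction, repeat_fraction,
             comorbidity_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(comorbidity_prevalence) &&
      !all(names(comorbidity_prevalence) %in% deyo_categories()$key)) {
    bad <- setdiff(names(comorbidity_prevalence), deyo_categories()$key)
    stop("unknown Deyo categories: ", paste(bad, collapse = ", "))
  }
  if (covid_positive_count < 0) stop("covid_positive_count must be >= 0")
  if (season_amp < 0) stop("season_amp must be >= 0")
  structure(list(
    seed = as.integer(seed),
    study_start = study_start, study_end = study_end,
    calendar = calendar, strata = strata,
    beta_wave = beta_wave, beta_after = beta_after,
    confound_rho = confound_rho, season_amp = season_amp,
    year_trend = year_trend, lag = lag,
    ltc_fraction = ltc_fraction, doa_fraction = doa_fraction,
    repeat_fraction = repeat_fraction,
    covid_positive_count = as.integer(covid_positive_count),
    comorbidity_prevalence = comorbidity_prevalence
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic ED cohort configuration\n")
  cat("  window:", format(x$study_start), "..", format(x$study_end), "\n")
  cat("  strata:", nrow(x$strata),
      sprintf("(total %.0f visits/day, %.1f deaths/day)",
              sum(x$strata$visit_rate), sum(x$strata$death_rate)), "\n")
  cat("  wave effects (visits/day):",
      paste(sprintf("%s=%g", names(x$beta_wave), x$beta_wave),
            collapse = ", "),
      sprintf(", after=%g", x$beta_after), "\n")
  cat(sprintf("  theta1 range: [%g, %g]; rho=%g; lag=%d\n",
              min(x$strata$theta1), max(x$strata$theta1),
              x$confound_rho, x$lag))
  invisible(x)
}

#' Default stratum table
#'
#' Twelve strata (six age bins by sex) with baseline daily visit and 28-day
#' death rates calibrated so the aggregate matches a large urban ED network:
#' about 5460 visits/day (2.0M visits/year) of which about 1760/day are aged
#' >= 65, and about 94 28-day deaths/day (34,000/year) concentrated in the
#' older strata. The three youngest age bins have mean daily deaths at or
#' below 1 and are therefore dropped by the stratum-exclusion rule, as
#' happens in real ED cohorts of this size.
#'
#' @param theta1 causal coefficient (deaths per visit) applied to every
#'   stratum; default -0.02.
#' @return data.frame usable as the `strata` argument of [sim_config()].
#' @export
default_strata <- function(theta1 = -0.02) {
  data.frame(
    age_group = rep(age_group_levels(), each = 2L),
    sex = rep(c("M", "F"), times = 6L),
    visit_rate = c(330, 280, 380, 420, 330, 360, 400, 390, 420, 390, 850, 910),
    death_rate = c(0.02, 0.015, 0.18, 0.10, 0.45, 0.30,
                   2.6, 1.5, 8.5, 4.5, 42, 34),
    theta1 = theta1,
    stringsAsFactors = FALSE
  )
}

default_comorbidity_prevalence <- function() {
  c(mi = 0.04, chf = 0.08, pvd = 0.02, cvd = 0.10, dementia = 0.08,
    copd = 0.12, rheum = 0.02, pud = 0.03, mild_liver = 0.02,
    dm = 0.15, dm_comp = 0.05, paralysis = 0.02, renal = 0.08,
    malignancy = 0.10, severe_liver = 0.01, mets = 0.03, aids = 0.002)
}

#' Default full-cohort configuration
#'
#' The standard study conditions: the 2016-2021 window, the illustrative
#' four-wave calendar, the twelve [default_strata()], aggregate wave
#' reductions of 1100-1500 visits/day, `theta1 = -0.02`, and confounding
#' `rho = 0.5`. `scale` multiplies all baseline rates, wave effects and the
#' seasonal amplitude jointly, preserving the relative structure while
#' shrinking the cohort for quick examples.
#'
#' @param seed integer RNG seed.
#' @param scale positive multiplier on rates and effects.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, scale = 1, ...) {
  stopifnot(scale > 0)
  strata <- default_strata()
  strata$visit_rate <- strata$visit_rate * scale
  strata$death_rate <- strata$death_rate * scale
  sim_config(seed = seed, strata = strata,
             beta_wave = c(wave1 = -1500, wave2 = -1300,
                           wave3 = -1100, wave4 = -1300) * scale,
             beta_after = -500 * scale,
             season_amp = 150 * scale,
             covid_positive_count = 3716L,
             ...)
}

#' Single-stratum benchmark configuration
#'
#' One >= 65 male stratum at about 3000 visits/day and 40 deaths/day over
#' the full six-year window — the scale used throughout the estimator
#' recovery and coverage studies. Wave effects are strong (400-800
#' visits/day) so the instruments are informative.
#'
#' @param seed integer RNG seed.
#' @param theta1 causal coefficient, deaths per visit.
#' @param confound_rho confounding correlation.
#' @param lag lag in days between visit change and death response.
#' @param beta_scale multiplier on the wave effects (instrument strength).
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
single_stratum_config <- function(seed = 1L, theta1 = -0.02,
                                  confound_rho = 0.5, lag = 0L,
                                  beta_scale = 1, ...) {
  sim_config(
    seed = seed,
    strata = data.frame(age_group = ">=65", sex = "M",
                        visit_rate = 3000, death_rate = 40,
                        theta1 = theta1, stringsAsFactors = FALSE),
    beta_wave = c(wave1 = -800, wave2 = -600,
                  wave3 = -500, wave4 = -650) * beta_scale,
    beta_after = -300 * beta_scale,
    season_amp = 80,
    confound_rho = confound_rho,
    lag = lag,
    ...
  )
}
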