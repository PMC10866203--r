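#' Simulate a dataset to disk
#'
#' Runs the synthetic generator and writes the full dataset bundle: one
#' daily-series CSV per stratum (`series_<age>_<sex>.csv`), the visit
#' records (`visit_records.csv`), the ground truth (`ground_truth.json`),
#' and a manifest JSON recording the configuration and its hash, so reruns
#' with the same seed and configuration are byte-identical and verifiably
#' so.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `manifest` (parsed), `paths`, and the
#'   in-memory `counts` result.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- generate_daily_counts(config)
  records <- generate_visit_records(config, counts)

  paths <- character(0)
  for (lab in names(counts$series)) {
    fn <- file.path(out_dir, paste0(
      "series_", gsub("[^0-9A-Za-z]+", "_", lab), ".csv"))
    write_daily_series(counts$series[[lab]], fn)
    paths <- c(paths, fn)
  }
  rec_path <- file.path(out_dir, "visit_records.csv")
  write_visit_records(records, rec_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(
    strata = as.data.frame(counts$truth),
    beta_wave = as.list(attr(counts$truth, "beta_wave")),
    beta_after = attr(counts$truth, "beta_after"),
    implied_total_excess = sum(counts$truth$implied_excess)
  ), truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_json <- config_json(config)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_strata = nrow(config$strata),
    n_records = nrow(records),
    files = basename(c(paths, rec_path, truth_path))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(manifest = manifest, counts = counts,
                 paths = c(paths, rec_path, truth_path, cfg_path,
                           manifest_path)))
}

config_json <- function(config) {
  jsonlite::toJSON(list(
    seed = config$seed,
    study_start = format(config$study_start),
    study_end = format(config$study_end),
    waves = lapply(config$calendar$waves, format),
    strata = config$strata,
    beta_wave = as.list(config$beta_wave),
    beta_after = config$beta_after,
    confound_rho = config$confound_rho,
    season_amp = config$season_amp,
    year_trend = config$year_trend,
    lag = config$lag,
    ltc_fraction = config$ltc_fraction,
    doa_fraction = config$doa_fraction,
    repeat_fraction = config$repeat_fraction,
    covid_positive_count = config$covid_positive_count,
    comorbidity_prevalence = as.list(config$comorbidity_prevalence)
  ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on a visit-record table: COVID-positive
#' exclusion, per-stratum daily tallies, stratum exclusion, the 2SLS lag
#' sweep with partial-F diagnostics, aggregation to total excess deaths
#' (with per-stratum visit reductions measured as the seasonally adjusted
#' same-period shortfall over the pandemic years), the DOA/DBA breakdown,
#' the incidence-rate comparison, and the comorbidity change table. Outputs
#' are written as CSV/JSON under `out_dir`; a failure in any stage aborts
#' with the stage named, retaining outputs already written.
#'
#' @param records visit record data.frame or path to a records CSV.
#' @param calendar a [wave_calendar()].
#' @param window `c(start, end)` study window.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param lags integer lags for the sweep (default 0:14).
#' @param baseline_years baseline years for seasonally adjusted changes.
#' @param pandemic_years years whose visit shortfall feeds the excess-death
#'   total.
#' @param se,ci_level passed to [fit_2sls()].
#' @param specs list of two [group_spec()]s for the incidence comparison,
#'   or `NULL` to skip.
#' @return invisibly, a list: `series` (all strata), `retained`, `fits`
#'   (lag-0 per stratum), `sweeps`, `excess` (a [total_excess()] object),
#'   `doa`, `incidence`, `comorbidity`, `summary`.
#' @export
run_pipeline <- function(records, calendar, window, out_dir = NULL,
                         lags = 0:14, baseline_years = 2016:2019,
                         pandemic_years = c(2020, 2021),
                         se = "classical", ci_level = 0.95,
                         specs = list(covid_group_spec(),
                                      precovid_group_spec())) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(records)) records <- stage("read", read_visit_records(records))
  window <- as.Date(window)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  records <- stage("exclude_covid", exclude_covid_positive(records,
                                                           quiet = TRUE))
  series <- stage("tally", tally_all_strata(records, window))
  retained <- stage("stratum_exclusion",
                    apply_stratum_exclusion(series, quiet = TRUE))
  if (length(retained) == 0L) {
    stop("pipeline stage 'stratum_exclusion' failed: no stratum retained",
         call. = FALSE)
  }

  sweeps <- list(); fits <- list()
  for (lab in names(retained)) {
    sweeps[[lab]] <- stage(paste0("iv_sweep[", lab, "]"),
                           lag_sweep(retained[[lab]], calendar, lags = lags,
                                     se = se, ci_level = ci_level))
    fits[[lab]] <- stage(paste0("iv_fit[", lab, "]"), suppressWarnings(
      fit_2sls(build_design(retained[[lab]], calendar, lag = min(lags),
                            stratum = lab), se = se, ci_level = ci_level)))
  }

  # pandemic-period visit reduction per retained stratum
  reductions <- stage("reductions", {
    sapply(names(retained), function(lab) {
      parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
      red <- 0
      for (y in pandemic_years) {
        ch <- seasonally_adjusted_change(
          records, c(as.Date(paste0(y, "-01-01")),
                     min(as.Date(paste0(y, "-12-31")), window[2L])),
          baseline_years = baseline_years, count = "visits",
          age_group = parts[1L], sex = parts[2L])
        red <- red - ch$change
      }
      red
    })
  })
  excess <- stage("total_excess",
                  total_excess(fits, reductions, ci_level = ci_level))

  doa <- stage("doa_breakdown",
               doa_breakdown(records, calendar,
                             years = intersect(
                               pandemic_years,
                               as.integer(format(window[1L], "%Y")):
                                 as.integer(format(window[2L], "%Y"))),
                             baseline_years = baseline_years))
  incidence <- if (!is.null(specs)) {
    stage("incidence", compare_incidence_rates(records, specs[[1L]],
                                               specs[[2L]]))
  }
  comorb <- stage("comorbidity",
                  comorbidity_change_table(records, calendar,
                                           year = pandemic_years[1L],
                                           baseline_years = baseline_years))

  summary <- list(
    total_excess = excess$total,
    total_excess_ci = c(excess$lower, excess$upper),
    strata = stats::setNames(lapply(names(fits), function(lab) {
      f <- fits[[lab]]
      l <- late_per_100(f)
      list(theta1 = unname(f$theta["attendance"]),
           se = unname(f$se["attendance"]),
           late_per_100 = l$estimate, late_ci = c(l$lower, l$upper),
           partial_F = f$partial_F, partial_F_p = f$partial_F_p,
           visit_reduction = unname(reductions[[lab]]))
    }), names(fits)),
    dropped_strata = attr(retained, "dropped")
  )

  if (!is.null(out_dir)) {
    sweep_tab <- do.call(rbind, lapply(names(sweeps), function(lab) {
      cbind(stratum = lab, as.data.frame(sweeps[[lab]]))
    }))
    data.table::fwrite(sweep_tab, file.path(out_dir, "iv_fits.csv"))
    data.table::fwrite(excess$strata,
                       file.path(out_dir, "excess_by_stratum.csv"))
    data.table::fwrite(doa, file.path(out_dir, "doa_breakdown.csv"))
    if (!is.null(incidence)) {
      data.table::fwrite(incidence$table,
                         file.path(out_dir, "incidence_comparison.csv"))
    }
    data.table::fwrite(comorb, file.path(out_dir, "comorbidity_changes.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(series = series, retained = retained, fits = fits,
                 sweeps = sweeps, reductions = reductions, excess = excess,
                 doa = doa, incidence = incidence, comorbidity = comorb,
                 summary = summary))
}
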