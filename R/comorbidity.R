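#' Deyo-Charlson comorbidity categories
#'
#' The 17 Charlson comorbidity categories in Deyo's ICD-9-CM adaptation,
#' with the short keys used throughout the package.
#'
#' @return data.frame with columns `key` and `label`.
#' @export
deyo_categories <- function() {
  data.frame(
    key = c("mi", "chf", "pvd", "cvd", "dementia", "copd", "rheum", "pud",
            "mild_liver", "dm", "dm_comp", "paralysis", "renal",
            "malignancy", "severe_liver", "mets", "aids"),
    label = c("Myocardial infarction", "Congestive heart failure",
              "Peripheral vascular disease", "Cerebrovascular disease",
              "Dementia", "Chronic pulmonary disease",
              "Rheumatologic disease", "Peptic ulcer disease",
              "Mild liver disease", "Diabetes",
              "Diabetes with complications", "Hemiplegia or paraplegia",
              "Renal disease", "Malignancy",
              "Moderate or severe liver disease", "Metastatic solid tumor",
              "AIDS"),
    stringsAsFactors = FALSE
  )
}

# cached code table, read from the shipped CSV resource
deyo_table_env <- new.env(parent = emptyenv())

#' Deyo ICD-9-CM code table
#'
#' The shipped Deyo (1992 Charlson adaptation) ICD-9-CM code list, one row
#' per (category, pattern). Patterns are undotted code prefixes: a code
#' matches a category when its normalized (dot-stripped, upper-case) form
#' starts with any of the category's patterns, so pattern `"428"` matches
#' `428.0`/`4280`. This mirrors the prefix semantics of range-based ICD
#' groupers. The table is a versioned resource and can be swapped by
#' passing an alternative table to [map_icd9_to_deyo()].
#'
#' @return data.frame with columns `category`, `icd9_pattern`, `match_type`.
#' @export
deyo_code_table <- function() {
  if (is.null(deyo_table_env$tab)) {
    path <- system.file("extdata", "deyo_icd9_1992.csv", package = "edexcess")
    if (path == "") path <- file.path("inst", "extdata", "deyo_icd9_1992.csv")
    deyo_table_env$tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                                          colClasses = "character")
  }
  deyo_table_env$tab
}

normalize_icd9 <- function(codes) {
  toupper(gsub("[. ]", "", trimws(codes)))
}

#' Map ICD-9-CM codes to a Deyo comorbidity profile
#'
#' Sets one boolean flag per Deyo-Charlson category from a list of ICD-9-CM
#' diagnosis codes. Codes may be dotted or undotted and are matched
#' case-insensitively by prefix against the shipped code table. Codes
#' matching no category are ignored (optionally reported via attribute
#' `unrecognized`), never an error. The mapping is deterministic,
#' idempotent, and invariant to code order and duplication.
#'
#' Category flags are raw: a patient can carry both `mild_liver` and
#' `severe_liver` (or `malignancy` and `mets`). In Charlson-score contexts
#' the severe form supersedes the mild one; this package tabulates category
#' membership only and leaves any hierarchy to the caller.
#'
#' @param codes character vector of ICD-9-CM codes (a single patient's
#'   code list).
#' @param table alternative code table in the [deyo_code_table()] layout.
#' @return named logical vector over the 17 category keys, with attribute
#'   `unrecognized` listing input codes that matched nothing.
#' @examples
#' map_icd9_to_deyo(c("428.0", "410.1"))[c("chf", "mi")]
#' @export
map_icd9_to_deyo <- function(codes, table = deyo_code_table()) {
  keys <- deyo_categories()$key
  flags <- stats::setNames(rep(FALSE, length(keys)), keys)
  codes <- codes[!is.na(codes) & nzchar(trimws(codes))]
  if (length(codes) == 0L) {
    attr(flags, "unrecognized") <- character(0)
    return(flags)
  }
  norm <- unique(normalize_icd9(codes))
  matched <- rep(FALSE, length(norm))
  for (k in keys) {
    pats <- table$icd9_pattern[table$category == k]
    if (length(pats) == 0L) next
    hit <- startsWith_any(norm, pats)
    if (any(hit)) flags[k] <- TRUE
    matched <- matched | hit
  }
  attr(flags, "unrecognized") <- norm[!matched]
  flags
}

startsWith_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

# one representative ICD-9-CM code list per category, for the simulator
deyo_code_samples <- function() {
  list(
    mi = c("410.1", "410.9", "412"),
    chf = c("428.0", "428.9"),
    pvd = c("443.9", "441.4"),
    cvd = c("434.91", "436", "438.9"),
    dementia = c("290.0", "290.4"),
    copd = c("491.21", "496", "493.9"),
    rheum = c("714.0", "710.0"),
    pud = c("531.9", "533.9"),
    mild_liver = c("571.5", "571.6"),
    dm = c("250.00", "250.02"),
    dm_comp = c("250.40", "250.60"),
    paralysis = c("342.9", "344.1"),
    renal = c("585", "582.9", "586"),
    malignancy = c("162.9", "153.9", "203.0"),
    severe_liver = c("572.2", "456.0"),
    mets = c("197.7", "198.5"),
    aids = c("042")
  )
}

#' Deyo profiles for a record table
#'
#' Vectorized [map_icd9_to_deyo()] over the `icd9_codes` column of a visit
#' record table (semicolon-joined code strings).
#'
#' @param icd9_codes character vector of semicolon-joined code strings.
#' @param table alternative code table in the [deyo_code_table()] layout.
#' @return logical matrix, one row per record, one column per category key.
#' @export
deyo_profiles <- function(icd9_codes, table = deyo_code_table()) {
  keys <- deyo_categories()$key
  n <- length(icd9_codes)
  out <- matrix(FALSE, n, length(keys), dimnames = list(NULL, keys))
  if (n == 0L) return(out)
  icd9_codes[is.na(icd9_codes)] <- ""
  # prefix-match each unique code once, then fold per record
  split_codes <- strsplit(normalize_icd9(icd9_codes), ";", fixed = TRUE)
  uniq <- unique(unlist(split_codes, use.names = FALSE))
  uniq <- uniq[nzchar(uniq)]
  if (length(uniq) == 0L) return(out)
  code_flags <- matrix(FALSE, length(uniq), length(keys),
                       dimnames = list(uniq, keys))
  for (k in keys) {
    pats <- table$icd9_pattern[table$category == k]
    if (length(pats)) code_flags[, k] <- startsWith_any(uniq, pats)
  }
  rec_id <- rep.int(seq_len(n), lengths(split_codes))
  code_id <- match(unlist(split_codes, use.names = FALSE), uniq)
  keep <- !is.na(code_id)
  rec_id <- rec_id[keep]; code_id <- code_id[keep]
  for (k in seq_along(keys)) {
    hits <- rec_id[code_flags[code_id, k]]
    if (length(hits)) out[unique(hits), k] <- TRUE
  }
  out
}

#' Per-comorbidity visit and death change table
#'
#' For patients aged >= 65 with DOA/DBA visits excluded, tabulates for each
#' Deyo category the seasonally adjusted change in episode visits and in
#' 28-day deaths for a pandemic year's wave and non-wave periods against the
#' same-period baseline-year average. Records are multi-labelled: a visit
#' with codes in two categories contributes to both rows.
#'
#' @param records visit record data.frame (see [generate_visit_records()]
#'   for the schema), COVID-positive records already excluded.
#' @param calendar a [wave_calendar()].
#' @param year pandemic year to evaluate (default 2020).
#' @param baseline_years years averaged into the baseline (default
#'   2016:2019).
#' @param min_age age threshold (default 65).
#' @return data.frame with one row per category x period (`wave`,
#'   `nonwave`): baseline and current visit and death counts, and percent
#'   changes. Categories with no baseline members are omitted (and listed in
#'   attribute `omitted`). A `diagonal` attribute carries the 1:1
#'   visit-change = death-change reference line endpoints for plotting.
#' @export
comorbidity_change_table <- function(records, calendar, year = 2020,
                                     baseline_years = 2016:2019,
                                     min_age = 65) {
  stopifnot(inherits(calendar, "wave_calendar"))
  rec <- records[records$age >= min_age & records$doa_dba == 0L, ]
  prof <- deyo_profiles(rec$icd9_codes)
  keys <- deyo_categories()$key
  periods <- year_wave_periods(calendar, year)
  rows <- list()
  omitted <- character(0)
  for (k in keys) {
    sub <- rec[prof[, k], ]
    if (nrow(sub) == 0L) { omitted <- c(omitted, k); next }
    for (pn in names(periods)) {
      vis <- seasonally_adjusted_change(sub, periods[[pn]],
                                        baseline_years = baseline_years,
                                        count = "visits")
      dth <- seasonally_adjusted_change(sub, periods[[pn]],
                                        baseline_years = baseline_years,
                                        count = "deaths28")
      rows[[length(rows) + 1L]] <- data.frame(
        category = k, period = pn,
        visits_baseline = vis$baseline, visits_current = vis$current,
        visit_change_pct = vis$pct_change,
        deaths_baseline = dth$baseline, deaths_current = dth$current,
        death_change_pct = dth$pct_change,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(0), period = character(0))
  rng <- if (nrow(out)) range(c(out$visit_change_pct, out$death_change_pct),
                              na.rm = TRUE) else c(-1, 1)
  attr(out, "diagonal") <- data.frame(x = rng, y = rng)
  attr(out, "omitted") <- omitted
  out
}

# wave / nonwave day sets of one calendar year as date vectors
year_wave_periods <- function(calendar, year) {
  days <- seq(as.Date(paste0(year, "-01-01")),
              as.Date(paste0(year, "-12-31")), by = "day")
  Z <- instrument_matrix(days, calendar)
  wave_cols <- setdiff(colnames(Z), "after_wave")
  in_wave <- rowSums(Z[, wave_cols, drop = FALSE]) > 0
  list(wave = days[in_wave], nonwave = days[!in_wave])
}
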