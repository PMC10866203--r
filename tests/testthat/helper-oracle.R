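# Independent oracles for the IV estimator, kept deliberately separate from
# the package's two-stage code path.

# Generalized 2SLS closed form: theta = (X' P_W X)^-1 X' P_W y, where
# X = [1, A, S] and W = [1, Z, S] (instruments plus exogenous covariates),
# P_W the projection onto the column space of W.
oracle_2sls <- function(A, D, Z, S = NULL) {
  n <- length(A)
  one <- rep(1, n)
  X <- cbind(one, A, S)
  W <- cbind(one, Z, S)
  PWX <- W %*% solve(crossprod(W), crossprod(W, X))
  as.numeric(solve(crossprod(PWX, X), crossprod(PWX, D)))
}

# Wald ratio for a single binary instrument, no covariates
wald_ratio <- function(A, D, z) {
  (mean(D[z == 1]) - mean(D[z == 0])) /
    (mean(A[z == 1]) - mean(A[z == 0]))
}

# hand-rolled iv_design for raw vectors (bypasses calendar construction)
manual_design <- function(A, D, Z, S = NULL, lag = 0L) {
  n <- length(A)
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  S <- if (is.null(S)) matrix(numeric(0), n, 0) else as.matrix(S)
  if (ncol(S) && is.null(colnames(S))) colnames(S) <- paste0("s", seq_len(ncol(S)))
  structure(list(A = as.numeric(A), D = as.numeric(D), Z = Z, S = S,
                 dates = as.Date("2020-01-01") + seq_len(n) - 1L,
                 lag = lag, stratum = NA_character_),
            class = "iv_design")
}

# small two-wave calendar inside a two-year window, for compact fixtures
small_calendar <- function() {
  wave_calendar(list(wave1 = c("2020-01-25", "2020-02-29"),
                     wave2 = c("2020-07-01", "2020-08-15")))
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed,
    study_start = "2019-01-01", study_end = "2020-12-31",
    calendar = small_calendar(),
    strata = data.frame(age_group = c(">=65", "45-54"), sex = c("M", "F"),
                        visit_rate = c(80, 50), death_rate = c(5, 2),
                        theta1 = -0.02, stringsAsFactors = FALSE),
    beta_wave = c(wave1 = -30, wave2 = -20), beta_after = -10,
    season_amp = 5, ...)
}

# minimal visit-record table with all schema columns
make_records <- function(patient_id, visit_date, age = 70, sex = "M",
                         ltc = 0L, doa_dba = 0L, covid_pcr = 0L,
                         icd9_codes = "", death_date = as.Date(NA)) {
  if (length(patient_id) == 0L) {
    age <- integer(0); sex <- character(0); ltc <- integer(0)
    doa_dba <- integer(0); covid_pcr <- integer(0)
    icd9_codes <- character(0); death_date <- as.Date(character(0))
  }
  data.frame(patient_id = patient_id, visit_date = as.Date(visit_date),
             age = age, sex = sex, ltc = ltc, doa_dba = doa_dba,
             covid_pcr = covid_pcr, icd9_codes = icd9_codes,
             death_date = as.Date(death_date), stringsAsFactors = FALSE)
}
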