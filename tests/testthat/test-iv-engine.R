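test_that("design building lags, trims and indexes as specified", {
  days <- seq(as.Date("2016-01-01"), as.Date("2021-12-31"), by = "day")
  ser <- data.frame(date = days, visits = seq_along(days) %% 50 + 10,
                    deaths28 = seq_along(days) %% 7)
  cal <- default_wave_calendar()

  d0 <- build_design(ser, cal, lag = 0)
  expect_equal(length(d0$A), 2192L)
  expect_equal(d0$D, as.numeric(ser$deaths28))  # lag 0: outcome untouched

  d5 <- build_design(ser, cal, lag = 5)
  expect_equal(length(d5$A), 2187L)             # 2192 - 5 aligned rows
  expect_equal(d5$D[1], as.numeric(ser$deaths28[6]))
  expect_equal(d5$A[1], as.numeric(ser$visits[1]))

  # seasonal covariates: Jan 1 -> t = 0, Jan 2 -> t = 1, 2016 -> year 0
  expect_equal(unname(d0$S[1, "t"]), 0)
  expect_equal(unname(d0$S[2, "t"]), 1)
  expect_equal(unname(d0$S[1, "year"]), 0)
  expect_equal(unname(d0$S[367, "year"]), 1)    # 2016 is a leap year
  expect_equal(d0$S[, "t2"], d0$S[, "t"]^2)

  # instruments: mutually exclusive wave columns, after-wave excludes waves
  Z <- d0$Z
  expect_true(all(Z %in% c(0L, 1L)))
  wave_cols <- setdiff(colnames(Z), "after_wave")
  expect_lte(max(rowSums(Z[, wave_cols])), 1L)
  expect_true(all(Z[, "after_wave"] + rowSums(Z[, wave_cols]) <= 1L))
  expect_true(all(Z[d0$dates < as.Date("2020-01-25"), ] == 0L))

  expect_error(build_design(ser[1:3, ], cal, lag = 10), "lag")
})

test_that("first stage recovers wave effects and flags rank deficiency", {
  # recovery of known beta over seeded replicates
  hits <- vapply(1:60, function(i) {
    sim <- generate_daily_counts(single_stratum_config(seed = i))
    d <- build_design(sim$series[[1]], sim$config$calendar)
    fs <- fit_first_stage(d)
    b <- fs$coef["wave1"]; se <- fs$se["wave1"]
    abs(b - (-800)) <= 1.96 * se
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # constant exposure: all slopes zero
  sim <- generate_daily_counts(single_stratum_config(seed = 1))
  d <- build_design(sim$series[[1]], sim$config$calendar)
  d$A <- rep(100, length(d$A))
  fs <- fit_first_stage(d)
  expect_equal(max(abs(fs$coef[-1])), 0, tolerance = 1e-8)

  # a wave absent from the window makes its column all-zero -> named error
  d$Z[, "wave3"] <- 0L
  expect_error(fit_first_stage(d), "wave3")
})

test_that("2SLS equals OLS under the identity instrument and the Wald ratio when just-identified", {
  set.seed(1)
  n <- 200
  A <- rnorm(n, 100, 10)
  D <- 5 - 0.03 * A + rnorm(n)
  # instrument identical to the exposure: theta1 is exactly the OLS slope
  fit <- fit_2sls(manual_design(A, D, Z = cbind(z = A)))
  ols <- unname(coef(lm(D ~ A))[2])
  expect_equal(unname(coef(fit)["attendance"]), ols, tolerance = 1e-10)

  # 12-row hand-computable just-identified case
  z <- rep(c(0, 1), each = 6)
  A12 <- c(30, 32, 28, 31, 29, 30, 20, 22, 18, 21, 19, 20)
  D12 <- c(3, 4, 2, 3, 3, 3, 5, 6, 4, 5, 5, 5)
  fit12 <- suppressWarnings(fit_2sls(manual_design(A12, D12, Z = cbind(z = z))))
  expect_equal(unname(coef(fit12)["attendance"]),
               wald_ratio(A12, D12, z), tolerance = 1e-10)
  # hand arithmetic: (5 - 3) / (20 - 30) = -0.2
  expect_equal(unname(coef(fit12)["attendance"]), -0.2, tolerance = 1e-10)
})

test_that("estimator matches the closed-form IV solution on random designs", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(40:120, 1)
    q <- sample(1:5, 1)
    Z <- matrix(rbinom(n * q, 1, 0.4), n, q)
    nS <- sample(0:3, 1)
    S <- if (nS > 0) matrix(rnorm(n * nS), n, nS) else NULL
    A <- 50 + Z %*% rnorm(q, -8, 2) +
      (if (nS) S %*% rnorm(nS) else 0) + rnorm(n, 0, 3)
    D <- 4 - 0.05 * A + (if (nS) S %*% rnorm(nS, 0, 0.2) else 0) + rnorm(n)
    ok <- tryCatch({
      fit <- suppressWarnings(fit_2sls(manual_design(A, D, Z, S)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next  # rank-deficient random draw
    oracle <- oracle_2sls(A, D, Z, S)
    expect_equal(unname(coef(fit)["attendance"]), oracle[2],
                 tolerance = 1e-8)
    expect_equal(unname(coef(fit)["(Intercept)"]), oracle[1],
                 tolerance = 1e-8)
  }
})

test_that("adding a constant to the instrument columns leaves theta1 unchanged", {
  sim <- generate_daily_counts(single_stratum_config(seed = 4))
  d <- build_design(sim$series[[1]], sim$config$calendar)
  fit <- fit_2sls(d)
  d2 <- d
  d2$Z <- d$Z + 3  # intercept absorbs the shift
  fit2 <- fit_2sls(d2)
  expect_equal(coef(fit2)["attendance"], coef(fit)["attendance"],
               tolerance = 1e-8)
})

test_that("partial F matches explicit RSS arithmetic on a 20-row fixture", {
  set.seed(7)
  n <- 20
  Z <- matrix(rbinom(n * 2, 1, 0.5), n, 2, dimnames = list(NULL, c("a", "b")))
  S <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s"))
  A <- 10 - 3 * Z[, 1] - 2 * Z[, 2] + S[, 1] + rnorm(n)
  d <- manual_design(A, rnorm(n), Z, S)
  res <- partial_f(d)
  # by hand from lm residual sums of squares
  rss_f <- sum(resid(lm(A ~ Z + S))^2)
  rss_r <- sum(resid(lm(A ~ S))^2)
  q <- 2; k <- 4
  F_hand <- ((rss_r - rss_f) / q) / (rss_f / (n - k))
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(F_hand, q, n - k, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("pure-noise instruments give F near 1; simulated waves give p < .05", {
  set.seed(3)
  res <- vapply(1:150, function(i) {
    n <- 400
    Z <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
    A <- rnorm(n, 100, 10)
    out <- partial_f(manual_design(A, rnorm(n), Z))
    c(out$F, out$p)
  }, numeric(2))
  # null behaviour: E[F] = df2/(df2 - 2) ~ 1, p uniform on (0, 1)
  expect_equal(mean(res[1, ]), 1, tolerance = 0.12)
  expect_equal(mean(res[2, ]), 0.5, tolerance = 0.1)

  sim <- generate_daily_counts(single_stratum_config(seed = 10))
  d <- build_design(sim$series[[1]], sim$config$calendar)
  expect_lt(partial_f(d)$p, 0.05)
})

test_that("LATE scaling turns theta1 into excess deaths per 100 reduced visits", {
  expect_equal(late_per_100(-0.02)$estimate, 2.0)
  expect_equal(late_per_100(0)$estimate, 0.0)
  # -0.0095 with CI (-0.0152, -0.0038): flip sign, scale, reorder
  se <- (0.0152 - 0.0038) / 2 / 1.96
  l <- late_per_100(-0.0095, se = se)
  expect_equal(l$estimate, 0.95)
  expect_equal(l$lower, 0.38, tolerance = 1e-6)
  expect_equal(l$upper, 1.52, tolerance = 1e-6)
  expect_lt(l$lower, l$upper)
})

test_that("confidence intervals are the 1.96-sigma normal approximation", {
  sim <- generate_daily_counts(single_stratum_config(seed = 6))
  fit <- fit_2sls(build_design(sim$series[[1]], sim$config$calendar))
  half <- fit$ci[, "upper"] - fit$theta
  expect_equal(unname(half), unname(1.96 * fit$se), tolerance = 1e-12)
})

test_that("lag sweep returns one aligned fit per lag and survives failures", {
  sim <- generate_daily_counts(single_stratum_config(seed = 2))
  sw <- lag_sweep(sim$series[[1]], sim$config$calendar, lags = 0:14)
  expect_equal(nrow(sw), 15L)
  expect_equal(sw$n, 2192L - 0:14)
  expect_true(all(is.na(sw$error)))
  # lag list [0]: identical to a direct lag-0 fit
  sw0 <- lag_sweep(sim$series[[1]], sim$config$calendar, lags = 0)
  direct <- fit_2sls(build_design(sim$series[[1]], sim$config$calendar))
  expect_equal(sw0$theta1, unname(coef(direct)["attendance"]))
  expect_equal(sw0$partial_F, direct$partial_F)
})

test_that("total excess aggregates stratum fits with independent variances", {
  mkfit <- function(theta1, se) {
    structure(list(theta = c(`(Intercept)` = 0, attendance = theta1),
                   se = c(`(Intercept)` = 0, attendance = se),
                   ci_level = 0.95),
              class = "twosls")
  }
  fits <- list(m = mkfit(-0.01, 0), f = mkfit(-0.02, 0))
  red <- c(m = 10000, f = 20000)
  ex <- total_excess(fits, red)
  expect_equal(ex$total, 500)           # 100 + 400, hand arithmetic
  expect_equal(ex$total_se, 0)
  expect_equal(ex$strata$excess, c(100, 400))

  # with uncertainty: pooled variance is the sum, CI symmetric
  fits2 <- list(m = mkfit(-0.01, 0.002), f = mkfit(-0.02, 0.003))
  ex2 <- total_excess(fits2, red)
  expect_equal(ex2$total_se, sqrt((10000 * 0.002)^2 + (20000 * 0.003)^2))
  expect_equal(ex2$upper - ex2$total, ex2$total - ex2$lower)
  # all-zero thetas: total 0, CI centred at 0
  ex0 <- total_excess(list(m = mkfit(0, 0.001), f = mkfit(0, 0.001)), red)
  expect_equal(ex0$total, 0)
  expect_equal(ex0$lower, -ex0$upper)

  expect_error(total_excess(fits, c(x = 1, y = 2)), "named")
})

test_that("model accessors behave like standard fit objects", {
  sim <- generate_daily_counts(single_stratum_config(seed = 8))
  d <- build_design(sim$series[[1]], sim$config$calendar)
  fit <- fit_2sls(d)
  expect_named(coef(fit), c("(Intercept)", "attendance", "year", "t", "t2", "t3"))
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  expect_equal(nrow(confint(fit)), 6L)
  expect_equal(length(fitted(fit)), fit$n)
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(predict(fit), as.numeric(cbind(1, d$A, d$S) %*% coef(fit)))
  expect_output(print(fit), "theta1")
  expect_output(print(summary(fit)), "Partial F")
})
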