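#' Build the instrumental-variable design for one stratum
#'
#' Assembles the row-aligned matrices the two-stage estimator consumes from
#' a daily series and a wave calendar: the exposure `A` (daily visits), the
#' lagged outcome `D[t] = deaths28[t + lag]`, five binary instruments
#' (after-wave and one per wave), and the four seasonal covariates (year
#' index, 0-based day-of-year `t`, `t^2`, `t^3`), all evaluated at the
#' exposure day. The trailing `lag` rows, whose outcome would fall outside
#' the series, are trimmed.
#'
#' @param series daily series data.frame (`date`, `visits`, `deaths28`).
#' @param calendar a [wave_calendar()].
#' @param lag outcome lag in days, 0-14.
#' @param year0 year mapped to seasonal index 0 (default: first year of the
#'   series).
#' @param stratum optional stratum label carried through to fits.
#' @return an object of class `iv_design` with elements `A`, `D`, `Z`
#'   (n x 5), `S` (n x 4), `dates`, `lag`, `stratum`.
#' @export
build_design <- function(series, calendar, lag = 0L, year0 = NULL,
                         stratum = NULL) {
  stopifnot(inherits(calendar, "wave_calendar"))
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be non-negative")
  n <- nrow(series)
  if (lag >= n) stop("lag (", lag, ") must be smaller than the series ",
                     "length (", n, ")")
  keep <- seq_len(n - lag)
  dates <- as.Date(series$date)[keep]
  structure(list(
    A = as.numeric(series$visits)[keep],
    D = as.numeric(series$deaths28)[keep + lag],
    Z = instrument_matrix(dates, calendar),
    S = seasonal_covariates(dates, year0 = year0 %||%
                              as.integer(format(series$date[1L], "%Y"))),
    dates = dates, lag = lag,
    stratum = stratum %||% attr(series, "stratum") %||% NA_character_
  ), class = "iv_design")
}

#' @export
print.iv_design <- function(x, ...) {
  cat("IV design: ", length(x$A), " days, lag ", x$lag,
      if (!is.na(x$stratum)) paste0(", stratum ", x$stratum), "\n", sep = "")
  invisible(x)
}

# OLS via QR with an explicit rank check that names collinear columns
ols_qr <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, y)
  fitted <- as.numeric(X %*% coef)
  list(coef = coef, fitted = fitted, residuals = y - fitted, qr = qr_x)
}

#' First-stage regression of exposure on instruments
#'
#' Ordinary least squares of daily visits on an intercept, the five binary
#' wave instruments, and the seasonal covariates. Errors explicitly when the
#' design is rank deficient (e.g. a wave absent from the window), naming the
#' collinear columns.
#'
#' @param design an [build_design()] result.
#' @return list with `coef` (named, instruments prefixed by their labels),
#'   `se`, `fitted` (the predicted exposure), `residuals`, `rss`.
#' @export
fit_first_stage <- function(design) {
  stopifnot(inherits(design, "iv_design"))
  X <- cbind(`(Intercept)` = 1, design$Z, design$S)
  fit <- ols_qr(X, design$A)
  n <- nrow(X); k <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (n - k)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  list(coef = fit$coef, se = se, fitted = fit$fitted,
       residuals = fit$residuals, rss = sum(fit$residuals^2),
       n = n, k = k)
}

#' Two-stage least squares fit
#'
#' The package's core estimator. Stage one regresses the exposure (daily ED
#' visits) on the five binary wave instruments plus seasonal covariates;
#' stage two regresses the (lagged) daily 28-day death count on the
#' predicted exposure plus the same covariates. The slope `theta1` on
#' predicted exposure is the local average treatment effect: deaths per
#' visit among wave-compliers. Standard errors are proper 2SLS errors — the
#' residual variance uses the *actual* exposure substituted into the
#' second-stage equation, with covariance `sigma2 * (Xhat' Xhat)^-1`
#' (classical, homoskedastic) or the HC1 sandwich when `se = "hc1"`.
#'
#' @param design an [build_design()] result.
#' @param se `"classical"` (default) or `"hc1"`.
#' @param ci_level confidence level (default 0.95; the CI is the normal
#'   approximation `estimate +/- 1.96 * SE`).
#' @param f_floor partial-F value below which a weak-instrument warning is
#'   attached to the fit (not an error).
#' @return an object of class `twosls`: coefficients, SEs, CIs, the
#'   first-stage fit, partial F and p, lag, stratum, `n`.
#' @examples
#' sim <- generate_daily_counts(single_stratum_config(seed = 1))
#' d <- build_design(sim$series[[1]], sim$config$calendar, lag = 0)
#' fit <- fit_2sls(d)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
fit_2sls <- function(design, se = c("classical", "hc1"), ci_level = 0.95,
                     f_floor = 10) {
  stopifnot(inherits(design, "iv_design"))
  se_type <- match.arg(se)
  fs <- fit_first_stage(design)

  Xhat <- cbind(`(Intercept)` = 1, attendance = fs$fitted, design$S)
  st2 <- ols_qr(Xhat, design$D)
  theta <- st2$coef
  n <- nrow(Xhat); k <- ncol(Xhat)

  # residuals with the actual exposure in place of the fitted one
  Xact <- cbind(`(Intercept)` = 1, attendance = design$A, design$S)
  resid_act <- design$D - as.numeric(Xact %*% theta)

  XtXinv <- chol2inv(qr.R(st2$qr))
  if (se_type == "classical") {
    sigma2 <- sum(resid_act^2) / (n - k)
    vcov_theta <- sigma2 * XtXinv
  } else {
    meat <- crossprod(Xhat * resid_act)
    vcov_theta <- XtXinv %*% meat %*% XtXinv * n / (n - k)
  }
  dimnames(vcov_theta) <- list(colnames(Xhat), colnames(Xhat))
  se_theta <- sqrt(diag(vcov_theta))
  z <- ci_z(ci_level)
  ci <- cbind(lower = theta - z * se_theta, upper = theta + z * se_theta)

  pf <- partial_f_from_stage(design, fs)
  fit <- structure(list(
    theta = theta, se = se_theta, vcov = vcov_theta, ci = ci,
    ci_level = ci_level, se_type = se_type,
    first_stage = fs,
    fitted = st2$fitted, residuals = resid_act,
    partial_F = pf$F, partial_F_p = pf$p,
    n = n, lag = design$lag, stratum = design$stratum,
    design = design
  ), class = "twosls")
  if (is.finite(pf$F) && pf$F < f_floor) {
    attr(fit, "weak_instruments") <- TRUE
    warning(sprintf("weak instruments: partial F = %.2f < %g", pf$F, f_floor))
  }
  fit
}

#' Partial F test of instrument strength
#'
#' Compares the first-stage regression with a restricted regression of the
#' exposure on the seasonal covariates only:
#' `F = [(RSS_r - RSS_f)/q] / [RSS_f/(n - k)]` with `q` instruments and `k`
#' full-model parameters, with p-value from the `F(q, n - k)` distribution.
#' Low values indicate weak instruments.
#'
#' @param design an [build_design()] result.
#' @param first_stage optional precomputed [fit_first_stage()] result.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
partial_f <- function(design, first_stage = NULL) {
  partial_f_from_stage(design, first_stage %||% fit_first_stage(design))
}

partial_f_from_stage <- function(design, fs) {
  Xr <- cbind(`(Intercept)` = 1, design$S)
  rss_r <- sum(ols_qr(Xr, design$A)$residuals^2)
  q <- ncol(design$Z)
  n <- fs$n; k <- fs$k
  if (n <= k) stop("not enough rows (", n, ") for ", k, " parameters")
  Fstat <- ((rss_r - fs$rss) / q) / (fs$rss / (n - k))
  list(F = Fstat, p = stats::pf(Fstat, q, n - k, lower.tail = FALSE),
       df1 = q, df2 = n - k)
}

#' @export
print.twosls <- function(x, ...) {
  cat("Two-stage least squares fit")
  if (!is.na(x$stratum)) cat(" — stratum ", x$stratum, sep = "")
  cat("\n  n = ", x$n, " days, lag = ", x$lag,
      ", SE = ", x$se_type, "\n", sep = "")
  cat(sprintf("  theta1 (deaths/visit): %.5f  [%.5f, %.5f]\n",
              x$theta["attendance"], x$ci["attendance", 1L],
              x$ci["attendance", 2L]))
  l <- late_per_100(x)
  cat(sprintf("  excess deaths per 100 reduced visits: %.3f  [%.3f, %.3f]\n",
              l$estimate, l$lower, l$upper))
  cat(sprintf("  first-stage partial F: %.1f (p %s)\n", x$partial_F,
              format.pval(x$partial_F_p, digits = 3)))
  invisible(x)
}

#' @export
summary.twosls <- function(object, ...) {
  tab <- data.frame(
    estimate = object$theta, se = object$se,
    lower = object$ci[, 1L], upper = object$ci[, 2L],
    row.names = names(object$theta)
  )
  out <- list(coefficients = tab,
              first_stage = data.frame(estimate = object$first_stage$coef,
                                       se = object$first_stage$se),
              partial_F = object$partial_F, partial_F_p = object$partial_F_p,
              n = object$n, lag = object$lag, stratum = object$stratum,
              se_type = object$se_type)
  class(out) <- "summary.twosls"
  out
}

#' @export
print.summary.twosls <- function(x, ...) {
  cat("2SLS second stage (n = ", x$n, ", lag = ", x$lag, ", SE: ",
      x$se_type, ")\n", sep = "")
  print(round(x$coefficients, 6))
  cat("\nFirst stage (exposure on instruments + seasonality)\n")
  print(round(x$first_stage, 4))
  cat(sprintf("\nPartial F: %.2f, p = %s\n", x$partial_F,
              format.pval(x$partial_F_p, digits = 3)))
  invisible(x)
}

#' @export
coef.twosls <- function(object, ...) object$theta

#' @export
vcov.twosls <- function(object, ...) object$vcov

#' @export
confint.twosls <- function(object, parm = NULL, level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$ci_level))) {
    z <- ci_z(level)
    ci <- cbind(lower = object$theta - z * object$se,
                upper = object$theta + z * object$se)
  } else ci <- object$ci
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.twosls <- function(object, ...) object$fitted

#' @export
residuals.twosls <- function(object, ...) object$residuals

#' Predicted daily 28-day deaths
#'
#' Evaluates the structural second-stage equation at the actual exposure:
#' `theta0 + theta1 * A + gamma' S`, for the fitted design or a new one.
#'
#' @param object a [fit_2sls()] fit.
#' @param newdesign optional `iv_design` to predict on.
#' @param ... unused.
#' @export
predict.twosls <- function(object, newdesign = NULL, ...) {
  d <- newdesign %||% object$design
  X <- cbind(1, d$A, d$S)
  as.numeric(X %*% object$theta)
}

#' Excess deaths per 100 reduced visits
#'
#' Rescales the second-stage slope into its epidemiological reading: with
#' `theta1 = -0.02`, a reduction of 100 visits on a day causes 2 excess
#' deaths (at the fit's lag). Returns `-100 * theta1` with the matching
#' normal CI, endpoints reordered so `lower < upper` after the sign flip.
#'
#' @param fit a [fit_2sls()] fit, or a numeric `theta1`.
#' @param se standard error of `theta1` when `fit` is numeric.
#' @param ci_level confidence level.
#' @return list with `estimate`, `lower`, `upper`.
#' @examples
#' late_per_100(-0.02)$estimate   # 2 excess deaths per 100 reduced visits
#' @export
late_per_100 <- function(fit, se = NULL, ci_level = 0.95) {
  if (inherits(fit, "twosls")) {
    theta1 <- unname(fit$theta["attendance"])
    se <- unname(fit$se["attendance"])
    ci_level <- fit$ci_level
  } else {
    theta1 <- as.numeric(fit)
    se <- se %||% 0
  }
  z <- ci_z(ci_level)
  ends <- sort(-100 * c(theta1 - z * se, theta1 + z * se))
  list(estimate = -100 * theta1, lower = ends[1L], upper = ends[2L])
}

#' Fit the model across a range of outcome lags
#'
#' Refits the 2SLS model with the outcome shifted by each lag in turn,
#' collecting the slope, CI and diagnostics per lag — the basis for a
#' theta-versus-lag profile. Per-lag failures are recorded and skipped, not
#' propagated.
#'
#' @param series daily series data.frame.
#' @param calendar a [wave_calendar()].
#' @param lags integer vector of lags (default 0:14).
#' @param ... passed to [fit_2sls()].
#' @return object of class `twosls_sweep`: a data.frame with one row per
#'   lag (`lag`, `theta1`, `se`, `lower`, `upper`, `late_per_100`,
#'   `partial_F`, `p`, `n`, `error`), with the fit objects in attribute
#'   `fits`.
#' @export
lag_sweep <- function(series, calendar, lags = 0:14, ...) {
  fits <- vector("list", length(lags))
  rows <- vector("list", length(lags))
  for (i in seq_along(lags)) {
    res <- tryCatch(
      fit_2sls(build_design(series, calendar, lag = lags[i]), ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(lag = lags[i], theta1 = NA_real_,
                              se = NA_real_, lower = NA_real_,
                              upper = NA_real_, late_per_100 = NA_real_,
                              partial_F = NA_real_, p = NA_real_,
                              n = NA_integer_,
                              error = conditionMessage(res))
    } else {
      fits[[i]] <- res
      l <- late_per_100(res)
      rows[[i]] <- data.frame(
        lag = lags[i],
        theta1 = unname(res$theta["attendance"]),
        se = unname(res$se["attendance"]),
        lower = unname(res$ci["attendance", 1L]),
        upper = unname(res$ci["attendance", 2L]),
        late_per_100 = l$estimate,
        partial_F = res$partial_F, p = res$partial_F_p,
        n = res$n, error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "stratum") <- attr(series, "stratum") %||% NA_character_
  class(out) <- c("twosls_sweep", "data.frame")
  out
}

#' @export
print.twosls_sweep <- function(x, ...) {
  cat("2SLS lag sweep (", nrow(x), " lags)\n", sep = "")
  print.data.frame(
    cbind(x[, c("lag", "theta1", "se", "lower", "upper", "partial_F")]),
    digits = 4, row.names = FALSE)
  invisible(x)
}

#' Plot a lag sweep
#'
#' Excess deaths per 100 reduced visits against lag, with the CI band.
#'
#' @param x a [lag_sweep()] result.
#' @param ... passed to [plot()].
#' @export
plot.twosls_sweep <- function(x, ...) {
  ok <- is.na(x$error)
  est <- -100 * x$theta1
  lo <- -100 * x$upper
  hi <- -100 * x$lower
  plot(x$lag[ok], est[ok], type = "n",
       ylim = range(c(lo[ok], hi[ok]), finite = TRUE),
       xlab = "lag (days)",
       ylab = "excess deaths per 100 reduced visits", ...)
  graphics::polygon(c(x$lag[ok], rev(x$lag[ok])), c(lo[ok], rev(hi[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(x$lag[ok], est[ok], type = "b", pch = 19,
                  col = "steelblue4")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Aggregate stratum fits into total excess deaths
#'
#' Converts each stratum's causal slope and observed visit reduction into
#' implied excess deaths (`-theta1 * reduction`) and pools them: the total
#' is the sum of stratum estimates and the total variance is the sum of
#' `reduction^2 * SE(theta1)^2`, treating strata as independent.
#'
#' @param fits named list of [fit_2sls()] fits, one per stratum.
#' @param reductions named numeric, total visits lost per stratum over the
#'   evaluation period (positive = fewer visits); names must match `fits`.
#' @param ci_level confidence level.
#' @return object of class `excess_deaths`: per-stratum table (`theta1`,
#'   `se`, excess with CI, excess per 100 reduced visits with CI) plus
#'   `total`, `total_se`, `lower`, `upper`.
#' @export
total_excess <- function(fits, reductions, ci_level = 0.95) {
  if (is.null(names(fits)) || is.null(names(reductions)) ||
      !setequal(names(fits), names(reductions))) {
    stop("`fits` and `reductions` must be named by the same strata")
  }
  reductions <- reductions[names(fits)]
  theta1 <- vapply(fits, function(f) unname(f$theta["attendance"]),
                   numeric(1))
  se1 <- vapply(fits, function(f) unname(f$se["attendance"]), numeric(1))
  excess <- -theta1 * reductions
  var_s <- reductions^2 * se1^2
  z <- ci_z(ci_level)
  per100 <- lapply(seq_along(fits), function(i)
    late_per_100(theta1[i], se1[i], ci_level))
  tab <- data.frame(
    stratum = names(fits), theta1 = theta1, se = se1,
    visit_reduction = reductions,
    excess = excess,
    excess_lower = excess - z * sqrt(var_s),
    excess_upper = excess + z * sqrt(var_s),
    late_per_100 = vapply(per100, `[[`, numeric(1), "estimate"),
    late_lower = vapply(per100, `[[`, numeric(1), "lower"),
    late_upper = vapply(per100, `[[`, numeric(1), "upper"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  total <- sum(excess)
  total_se <- sqrt(sum(var_s))
  structure(list(
    strata = tab, total = total, total_se = total_se,
    lower = total - z * total_se, upper = total + z * total_se,
    ci_level = ci_level
  ), class = "excess_deaths")
}

#' @export
print.excess_deaths <- function(x, ...) {
  cat("Excess 28-day deaths implied by visit reductions\n")
  print(x$strata[, c("stratum", "theta1", "visit_reduction", "excess",
                     "excess_lower", "excess_upper")],
        digits = 4, row.names = FALSE)
  cat(sprintf("\nTotal: %.0f (%d%% CI %.0f to %.0f)\n", x$total,
              round(100 * x$ci_level), x$lower, x$upper))
  invisible(x)
}
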