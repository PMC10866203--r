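---
title: "Estimating avoidance-driven excess ED mortality: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating avoidance-driven excess ED mortality: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edexcess)
```

## The estimation problem

During pandemic waves, emergency-department (ED) attendance drops sharply
while service capacity stays intact: people avoid hospitals. Some missed
visits become deaths. The quantity of interest is the causal slope
$\theta_1$ (deaths per visit) linking daily ED visits $A_t$ to daily
28-day deaths $D_{t+i}$, where a 28-day death is a death registered within
28 whole days (inclusive at 0 and 28) of the decedent's **last** ED visit
and is tallied on that visit's date. Tallying by last visit date keeps the
causal ordering — the reduced visit precedes the death it may have caused —
and prevents double counting when a patient visits repeatedly.

Ordinary least squares of $D$ on $A$ is confounded: daily severity mix,
weather, and epidemic anxiety move both series. The package therefore uses
two-stage least squares with five binary instruments derived from a wave
calendar: one indicator per wave (1 inside the closed government-designated
interval) and an after-wave indicator (1 on non-wave days strictly after
the first wave's end). Days before the first wave carry all-zero
instruments and anchor the baseline. The instruments are valid to the
extent that wave designations shift attendance abruptly (relevance,
checked with the first-stage partial F) and affect non-COVID mortality
only through attendance (exclusion; supported by removing PCR-positive
visits from the cohort).

Both stages adjust for smooth seasonality with four terms evaluated at the
exposure day: a year index (first study year = 0), the 0-based day-of-year
$t$, $t^2$ and $t^3$. Evaluating the seasonal terms at the exposure day —
rather than the outcome day $t+i$ — keeps the two stages' covariate sets
identical, which is what the two-equation structural model implies; for
lags of at most 14 days the polynomial terms barely move, so the choice is
numerically immaterial but conceptually cleaner.

## The estimator and its numerics

Stage one regresses $A$ on $[1, Z, S]$; stage two regresses the lagged
outcome on $[1, \hat A, S]$. Both stages use QR decompositions; rank
deficiency (e.g. a wave absent from the fitted window) raises an error
naming the collinear columns rather than silently dropping them. The
second-stage covariance is the proper 2SLS covariance: residuals are
evaluated with the *actual* exposure substituted into the fitted equation,
$\hat\sigma^2 = \|D - X\hat\theta\|^2/(n-k)$ with $X = [1, A, S]$, and
$\widehat{\mathrm{cov}} = \hat\sigma^2 (\hat X'\hat X)^{-1}$. Classical
homoskedastic errors are the default, matching standard IV-regression
software defaults; an HC1 sandwich is available via `fit_2sls(se = "hc1")`
for sensitivity checks. Confidence intervals are the conventional normal
approximation, $\pm 1.96\,\mathrm{SE}$ at the default 95% level.

The slope is reported both raw and as $-100\,\theta_1$, *excess deaths per
100 reduced visits*, with CI endpoints reordered after the sign flip.
Instrument strength is the partial F comparing the first stage with a
seasonal-covariates-only regression, $q = 5$ numerator degrees of freedom;
fits with partial F below 10 (the usual weak-instrument rule of thumb,
configurable) carry a warning. Lagged outcomes shift $D$ forward by $i$
days and trim the trailing $i$ rows — the series is never wrapped.

Aggregation to total excess deaths multiplies each retained stratum's
$\hat\theta_1$ by its observed visit reduction (the seasonally adjusted
same-period shortfall over the pandemic years) and sums; the pooled
variance is the sum of $\text{reduction}^2 \times \mathrm{SE}(\theta_1)^2$,
i.e. strata are treated as independent. Cross-stratum error correlation
(shared shocks) would widen the interval; with no way to estimate it from
per-stratum fits, independence is the documented assumption.

Strata with mean daily 28-day mortality at or below 1 over the full window
are excluded before fitting (the threshold is inclusive): with deaths that
sparse the linear model's error structure is dominated by integer noise
and the fit is unstable. Under the default cohort conditions this removes
the 0–17, 18–34 and 35–44 age bins of both sexes.

## What the synthetic cohort emulates

The generator simulates exactly the structural model the estimator
assumes, with known parameters, so recovery is a meaningful test:

$$A_t = \mu_A(t) + \textstyle\sum_k \beta_k Z_{kt} + u_t, \qquad
D_{t+i} = \mu_D(t) + \theta_1\,(A_t - \mathbb E[A_t \mid \text{no wave}])
+ v_t,$$

with $(u_t, v_t)$ jointly Gaussian, $\mathrm{corr}(u, v) = \rho$, and
standard deviations $\sqrt{\mu}$ (Poisson-like scaling). $\mu_A(t)$
combines the stratum baseline rate, a +0.5%/year drift, and a sinusoidal
seasonal term; noise is applied on the linear scale and counts are rounded
and clipped at zero, matching the linear model the estimator fits rather
than a log-link count process. At the default scales (hundreds to
thousands of visits/day) the rounding bias is far below the recovery
tolerance; configurations whose expected counts go negative on more than
1% of stratum-days are rejected as implausible. Daily deaths are capped at
the day's visits because a 28-day death must have a same-day last visit.

Nonzero $\rho$ is the confounder: it biases the OLS slope by
$\rho\,\sigma_v/\sigma_u$ (the sign of $\rho$) while leaving the IV
estimator consistent — the acceptance suite verifies both directions.
The benchmark conditions used throughout the recovery studies are one
≥65 stratum at 3000 visits/day and 40 deaths/day over 2016–2021
(`single_stratum_config()`), $\theta_1 = -0.02$, $\rho = 0.5$, wave
effects of 400–800 visits/day. The full default cohort
(`default_sim_config()`) has 12 strata totalling ~5460 visits/day and
~94 deaths/day, apportioning aggregate wave effects of 1100–1500
visits/day to strata by visit-rate share — a single-stratum configuration
therefore receives the full aggregate effect, which is what the
benchmark conditions assume.

Record-level expansion adds the registry texture the ETL needs: repeat
visitors (20% of visits by default, drawn from a rolling pool), decedents
chosen among each day's distinct visitors with death dates 0–28 days
after the last visit, DOA/DBA decedents (15% of decedents) dying on the
visit day, LTC flags for ≥65 patients (15%), Deyo-category diagnosis
codes drawn per configured prevalence, and PCR-positive visits. The
PCR-positive records are emitted *on top of* the daily series, because
the series defines the analysis (non-COVID) population: after the ETL's
exclusion step the tally reproduces the series exactly, which is the
round-trip invariant the tests assert.

What the generator does **not** emulate: epidemic case curves,
overdispersed or autocorrelated count noise, cause-of-death structure,
hospital-level heterogeneity, or any behavioural model of avoidance. A
passing recovery study therefore shows the estimator is correct *under
its own assumptions*; it cannot show that a real registry satisfies them.

## Wave calendar and period analytics

The shipped calendar (four waves between 2020-01-25 and 2021-02-18) is
illustrative, shaped like Hong Kong's four waves; real analyses must
supply the official government-designated dates via `wave_calendar()`.

Seasonally adjusted changes compare a period's count with the mean count
over the same calendar-day window in each baseline year (2016–2019 by
default), excluding February 29 when the baseline year lacks it. The same
operation, `period_change()`, backs every emitted table row, and every row
satisfies $|pct - 100\,\Delta/\text{baseline}| < 0.05$.

The individual-level incidence-rate comparison takes DOA/DBA decedents
aged ≥65 whose qualifying visit falls in a group window, keeps those with
at least two control-period visits, and classifies each by treatment- vs
control-period visit rate: `increase` iff treatment > control, `no_visits`
iff zero treatment-period visits, `reduction` otherwise — so exact rate
ties (with visits) land in `reduction`; the three categories always
partition the eligible set. The between-group test is a pooled
two-proportion z (each category count over the group's eligible total);
an unpooled variant is a flag away. The source tables never state the
exact test construction, so this interpretation is documented rather than
claimed.

## Comorbidity mapping

ICD-9-CM codes are mapped to the 17 Deyo (1992) Charlson categories with a
versioned CSV code table shipped in `inst/extdata/` (category, pattern,
match type). Codes are normalized (dots stripped, case folded) and matched
by prefix, so `428` covers `428.0`/`4280`; range entries (e.g. malignancy
140–208) are expanded to prefix lists. Unrecognized codes are reported,
never fatal. Flags are raw category memberships: severe liver disease does
not unset mild liver disease — in Charlson-score contexts the severe form
supersedes, and that hierarchy is left to the caller because the analyses
here tabulate per-category visit/death changes, in which a patient may
legitimately appear in several categories.

## Problem sizes and test design

The validation studies are sized to be decisive yet quick: parameter
recovery and CI coverage use 100 seeded replicates of the 2192-day
single-stratum benchmark (coverage must reach at least 90/100), lag
localization uses 100 replicates of an effect injected at lag 5 swept over
lags 0–10, the estimator-vs-oracle comparison uses 50 random small designs
at $10^{-8}$ relative tolerance against an independent closed-form
projection implementation, and the ETL round-trip runs on a two-stratum,
two-year cohort. The full suite completes in well under a minute.

## Known limitations

- The LATE interpretation is local: $\hat\theta_1$ speaks for
  wave-compliers, and monotonicity (no one visiting *because* of a wave)
  is assumed per stratum, not testable here.
- Classical SEs ignore serial correlation in the daily series; the HC1
  option addresses heteroskedasticity only.
- Independence pooling across strata likely understates the total-excess
  CI width when shocks are shared.
- The synthetic cohort is a stand-in with a stated noise model, not a
  claim about any real registry's data-generating process.
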