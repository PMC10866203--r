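test_that("period change reproduces printed cohort arithmetic", {
  # zero change
  expect_equal(period_change(100, 100)$pct_change, 0)
  # total ED visits, 2020 vs 2016-2019 average
  ch <- period_change(2142609, 1594493)
  expect_equal(ch$change, -548116)
  expect_equal(ch$pct_change, 100 * -548116 / 2142609)
  # non-LTC DOA/DBA increase: +1284 on 3026 is +42.4%
  ch2 <- period_change(3026, 3026 + 1284)
  expect_equal(round(ch2$pct_change, 1), 42.4)
  # zero baseline flagged, percent undefined
  ch0 <- period_change(0, 5)
  expect_true(is.na(ch0$pct_change))
  expect_true(isTRUE(attr(ch0, "zero_baseline")))
})

test_that("percent change stays consistent with counts on emitted rows", {
  set.seed(2)
  base <- sample(50:5000, 50)
  cur <- base + sample(-500:500, 50)
  tab <- period_change(base, cur)
  expect_true(all(abs(tab$pct_change - 100 * tab$change / tab$baseline)
                  < 0.05))
})

test_that("seasonally adjusted change averages same-calendar-day baselines", {
  # two baseline years with known counts, one current year
  rec <- rbind(
    make_records(sprintf("a%d", 1:10), "2018-03-05"),
    make_records(sprintf("b%d", 1:20), "2019-03-05"),
    make_records(sprintf("c%d", 1:12), "2020-03-05")
  )
  ch <- seasonally_adjusted_change(
    rec, c(as.Date("2020-03-01"), as.Date("2020-03-10")),
    baseline_years = 2018:2019, count = "visits")
  expect_equal(ch$baseline, 15)     # mean(10, 20)
  expect_equal(ch$current, 12)
  expect_equal(ch$change, -3)
  expect_equal(ch$pct_change, -20)
  # Feb 29 window works against non-leap baselines
  rec2 <- make_records("x", "2020-02-29")
  ch2 <- seasonally_adjusted_change(
    rec2, c(as.Date("2020-02-28"), as.Date("2020-02-29")),
    baseline_years = 2018:2019, count = "visits")
  expect_equal(ch2$baseline, 0)
  expect_error(seasonally_adjusted_change(
    rec, c(as.Date("2035-01-01"), as.Date("2035-01-10"))), "outside")
})

test_that("death changes use the last-visit tally within the period", {
  rec <- rbind(
    make_records("p1", c("2019-06-01", "2019-06-10"),
                 death_date = "2019-06-20"),
    make_records("p2", "2020-06-10", death_date = "2020-06-15"),
    make_records("p3", "2020-06-12")
  )
  ch <- seasonally_adjusted_change(
    rec, c(as.Date("2020-06-01"), as.Date("2020-06-30")),
    baseline_years = 2019, count = "deaths28")
  expect_equal(ch$baseline, 1)   # p1, by last visit 2019-06-10
  expect_equal(ch$current, 1)    # p2
})

test_that("DOA breakdown enumerates a hand-built fixture", {
  cal <- small_calendar()
  # >=65 decedents: baseline year 2019 vs pandemic 2020, wave1 window days
  rec <- rbind(
    # 2019 wave1-equivalent days (Jan 25 - Feb 28): 2 DOA deaths, 1 non-DOA
    make_records(c("d1", "d2"), c("2019-02-01", "2019-02-10"),
                 doa_dba = 1L, death_date = c("2019-02-01", "2019-02-10")),
    make_records("d3", "2019-02-15", death_date = "2019-03-01"),
    # 2020 wave days: 3 DOA deaths, 1 non-DOA
    make_records(c("d4", "d5", "d6"),
                 c("2020-02-01", "2020-02-05", "2020-02-20"),
                 doa_dba = 1L,
                 death_date = c("2020-02-01", "2020-02-05", "2020-02-20")),
    make_records("d7", "2020-02-10", death_date = "2020-02-20"),
    # young decedent: must not contribute
    make_records("y1", "2020-02-11", age = 30, doa_dba = 1L,
                 death_date = "2020-02-11")
  )
  tab <- doa_breakdown(rec, cal, years = 2020, baseline_years = 2019)
  doa_wave <- tab[tab$doa_dba == 1L & tab$period == "wave", ]
  expect_equal(doa_wave$baseline, 2)
  expect_equal(doa_wave$current, 3)
  expect_equal(doa_wave$change, 1)
  expect_equal(doa_wave$pct_change, 50)
  non_wave <- tab[tab$doa_dba == 0L & tab$period == "wave", ]
  expect_equal(non_wave$baseline, 1)
  expect_equal(non_wave$current, 1)
  # all-zero fixture: all changes 0
  none <- make_records("z", "2020-05-05")
  tab0 <- doa_breakdown(none, cal, years = 2020, baseline_years = 2019)
  expect_true(all(tab0$change == 0))
})

test_that("incidence rate is visits over period length", {
  p <- as.Date(c("2020-01-01", "2020-04-09"))  # 100 days
  expect_equal(incidence_rate(as.Date(c("2020-02-01", "2020-03-01")), p),
               0.02)
  expect_equal(incidence_rate(as.Date(character(0)), p), 0)
  p181 <- as.Date(c("2019-01-01", "2019-06-30"))  # 181 days
  expect_equal(incidence_rate(rep(as.Date("2019-02-01"), 5), p181), 5 / 181)
})

test_that("decedent categorization follows the eligibility and tie rules", {
  # control and treatment both 181 days long, so exact rate ties can occur
  spec <- group_spec(doa_window = c("2020-07-01", "2021-07-01"),
                     control = c("2019-01-01", "2019-06-30"),
                     treatment = c("2020-01-01", "2020-06-29"))
  ctrl_days <- function(n) as.Date("2019-03-01") + seq_len(n)
  trt_days <- function(n) as.Date("2020-02-01") + seq_len(n)
  doa_visit <- function(id) make_records(id, "2020-08-01", doa_dba = 1L,
                                         death_date = "2020-08-01")
  rec <- rbind(
    # p1: 2 control visits, 0 treatment -> no_visits
    make_records("p1", ctrl_days(2)), doa_visit("p1"),
    # p2: 2 control, many treatment -> increase
    make_records("p2", ctrl_days(2)), make_records("p2", trt_days(8)),
    doa_visit("p2"),
    # p3: 4 control, 1 treatment -> reduction
    make_records("p3", ctrl_days(4)), make_records("p3", trt_days(1)),
    doa_visit("p3"),
    # p4: only 1 control visit -> ineligible
    make_records("p4", ctrl_days(1)), doa_visit("p4"),
    # p5: non-DOA death -> not in the group
    make_records("p5", ctrl_days(3), death_date = "2020-08-10"),
    # p6: exact rate tie (2 visits in each 181-day period) -> reduction
    make_records("p6", ctrl_days(2)), make_records("p6", trt_days(2)),
    doa_visit("p6")
  )
  out <- categorize_decedents(rec, spec)
  expect_equal(out$eligible, 4L)
  expect_equal(unname(out$counts["no_visits"]), 1L)
  expect_equal(unname(out$counts["increase"]), 1L)
  expect_equal(unname(out$counts["reduction"]), 2L)
  expect_equal(sum(out$counts), out$eligible)  # partition
  expect_false("p4" %in% out$patients$patient_id)
  expect_false("p5" %in% out$patients$patient_id)
  # ties with treatment visits land in reduction: equal rates, tn > 0
  tie <- out$patients[out$patients$patient_id == "p6", ]
  expect_equal(tie$category, "reduction")

  # overlapping periods rejected
  expect_error(group_spec(doa_window = c("2020-07-01", "2021-07-01"),
                          control = c("2019-01-01", "2020-02-01"),
                          treatment = c("2020-01-01", "2020-06-30")),
               "overlap")
})

test_that("two-proportion z test matches direct formula evaluation", {
  # equal proportions: z = 0, p = 1
  eq <- two_sample_z(10, 100, 20, 200)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  # direct pooled-formula evaluation on printed incidence-category counts
  zt <- two_sample_z(194, 928, 222, 658)
  p1 <- 194 / 928; p2 <- 222 / 658
  p <- (194 + 222) / (928 + 658)
  z_hand <- (p1 - p2) / sqrt(p * (1 - p) * (1 / 928 + 1 / 658))
  expect_equal(zt$z, z_hand, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)

  # antisymmetry
  a <- two_sample_z(30, 90, 50, 110)
  b <- two_sample_z(50, 110, 30, 90)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)

  # degenerate pooled proportion flagged
  d0 <- two_sample_z(0, 50, 0, 60)
  expect_true(d0$degenerate)
  expect_true(is.na(d0$p))

  # unpooled variant differs but agrees in sign
  up <- two_sample_z(30, 90, 50, 110, pooled = FALSE)
  expect_equal(sign(up$z), sign(a$z))
})

test_that("group comparison assembles per-category z tests", {
  cfg <- small_sim_config(seed = 31, doa_fraction = 0.5,
                          repeat_fraction = 0.5)
  rec <- generate_visit_records(cfg, generate_daily_counts(cfg))
  spec1 <- group_spec(doa_window = c("2020-06-01", "2020-12-31"),
                      control = c("2019-01-01", "2019-12-31"),
                      treatment = c("2020-01-01", "2020-05-31"),
                      label = "late")
  spec2 <- group_spec(doa_window = c("2019-06-01", "2019-12-31"),
                      control = c("2019-01-01", "2019-05-31"),
                      treatment = c("2019-06-01", "2019-12-31"),
                      label = "early")
  cmp <- compare_incidence_rates(rec, spec1, spec2)
  expect_equal(nrow(cmp$table), 3L)
  expect_equal(sum(cmp$table$n1), cmp$group1$eligible)
  expect_equal(sum(cmp$table$n2), cmp$group2$eligible)
})
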