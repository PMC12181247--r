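test_that("cohort years run from 01 August through 31 July", {
  expect_equal(assign_cohort_year(as.Date("2014-08-01")), 2014L)
  expect_equal(assign_cohort_year(as.Date("2015-07-31")), 2014L)
  expect_equal(assign_cohort_year(as.Date("2015-08-01")), 2015L)
  expect_equal(assign_cohort_year(as.Date(c("2014-12-31", "2015-01-01"))),
               c(2014L, 2014L))
})

test_that("cohort sums accumulate day-degrees and split boundary events by day", {
  s <- flat_series(5, "2012-01-01", "2016-12-31")
  cl <- build_climatology(s, smooth_span = 0)  # exact collapsed envelope
  add <- function(s, start, len, by) {
    i <- match(as.Date(start), s$dates)
    s$values[i:(i + len - 1)] <- s$values[i:(i + len - 1)] + by
    s
  }
  # two positive events of +5.0 and +2.5 threshold day-degrees in one cohort
  s1 <- add(s, "2013-09-01", 5, 1)       # +5
  s1 <- add(s1, "2014-02-01", 5, 0.5)    # +2.5
  ev <- detect_events(s1, cl)
  summ <- cohort_cumulative(ev, s1, cl, baseline = "threshold")
  expect_equal(summ$positive_sum[summ$cohort_year == 2013], 7.5)
  expect_equal(summ$n_anomaly_units[summ$cohort_year == 2013], 10L)
  # anomaly-free cohorts report zeros
  expect_equal(summ$net_sum[summ$cohort_year == 2015], 0)
  expect_true(all(summ$positive_sum >= 0 & summ$negative_sum <= 0))

  # an event spanning 30 Jul - 03 Aug splits between cohorts, conserving total
  s2 <- add(s, "2014-07-28", 7, 2)
  ev2 <- detect_events(s2, cl)
  expect_equal(nrow(ev2), 1L)
  summ2 <- cohort_cumulative(ev2, s2, cl, baseline = "threshold")
  expect_equal(summ2$positive_sum[summ2$cohort_year == 2013], 8)  # 4 days x 2
  expect_equal(summ2$positive_sum[summ2$cohort_year == 2014], 6)  # 3 days x 2
  expect_equal(sum(summ2$positive_sum), ev2$day_degrees_threshold)
})

test_that("cohort ranking uses ascending average ranks", {
  expect_equal(rank_cohorts(c(-271, -50, 10, 200)), c(1, 2, 3, 4))
  expect_equal(rank_cohorts(c(5, 5, 1)), c(2.5, 2.5, 1))
  expect_equal(rank_cohorts(rep(3, 5)), rep(3, 5))
  summ <- data.frame(cohort_year = 2012:2015, net_sum = c(4, -2, 7, 0))
  class(summ) <- c("cohort_summary", "data.frame")
  expect_equal(rank_cohorts(summ), c(3, 1, 4, 2))
})

test_that("rank regression reproduces the analytic worked examples", {
  x <- 1:8
  r1 <- rank_regression(x, c(3, 4, 1, 2, 5, 6, 7, 8))  # sum d^2 = 16
  expect_equal(round(r1$F, 2), 11.41)
  expect_equal(round(r1$slope, 2), 0.81)
  expect_equal(round(r1$t_value, 2), 3.38)
  expect_equal(r1$df2, 6L)

  r2 <- rank_regression(x, c(4, 2, 3, 1, 5, 6, 7, 8))  # sum d^2 = 18
  expect_equal(round(r2$F, 2), 9.68)
  expect_equal(round(r2$adj_r2, 2), 0.55)

  expect_equal(r1$F, r1$t_value^2)
  expect_equal(r1$adj_r2, 1 - (1 - r1$r2) * 7 / 6)
})

test_that("degenerate rank-regression inputs follow the stated conventions", {
  x <- 1:8
  perfect <- rank_regression(x, x)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$r2, 1)
  expect_true(is.infinite(perfect$F))
  expect_equal(perfect$p_value, 0)
  expect_equal(rank_regression(x, rev(x))$slope, -1)
  expect_error(rank_regression(1:3, 1:4), "length")
  expect_error(rank_regression(1:2, 1:2), "at least 3")
  expect_error(rank_regression(rep(1, 4), 1:4), "variance")
})

test_that("rank-OLS slope equals Spearman correlation for untied ranks", {
  set.seed(61)
  for (rep_i in 1:100) {
    n <- sample(5:12, 1)
    x <- sample(n); y <- sample(n)
    r <- rank_regression(x, y)
    rho <- cor(x, y, method = "spearman")
    expect_equal(r$slope, rho, tolerance = 1e-12)
    if (abs(rho) < 1)
      expect_equal(r$F, (n - 2) * rho^2 / (1 - rho^2), tolerance = 1e-9)
    if (n == 8)
      expect_equal(r$slope, 1 - sum((x - y)^2) / 84, tolerance = 1e-12)
  }
})

test_that("Mann-Kendall handles monotone, mixed and tied sequences", {
  r_up <- mann_kendall(c(1, 2, 3, 4))
  expect_equal(r_up$tau, 1)
  expect_equal(r_up$s_statistic, 6L)
  expect_equal(mann_kendall(c(4, 3, 2, 1))$tau, -1)
  r <- mann_kendall(c(3, 1, 2, 4))
  expect_equal(r$s_statistic, 2L)
  expect_equal(r$tau, 1 / 3)
  # tie-corrected tau stays within [-1, 1]
  rt <- mann_kendall(c(1, 2, 2, 3, 1, 4, 4, 5, 6, 7, 8))
  expect_true(abs(rt$tau) <= 1)
  expect_identical(rt$method, "normal approximation")
  expect_error(mann_kendall(c(1, 2)), "at least 3")
})

test_that("Mann-Kendall S matches exhaustive pair enumeration", {
  set.seed(62)
  for (rep_i in 1:200) {
    n <- sample(3:8, 1)
    x <- rnorm(n)
    r <- mann_kendall(x)
    expect_equal(r$s_statistic, bf_mk_s(x))
  }
})

test_that("Mann-Kendall agrees with the Kendall correlation test against time", {
  set.seed(63)
  for (rep_i in 1:25) {
    x <- rnorm(9)
    r <- mann_kendall(x)
    ct <- suppressWarnings(cor.test(seq_along(x), x, method = "kendall"))
    expect_equal(r$tau, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)  # both exact at n=9
  }
  # large-n normal approximation tracks cor.test's continuity-corrected z
  x <- rnorm(40)
  r <- mann_kendall(x)
  ct <- suppressWarnings(cor.test(seq_along(x), x, method = "kendall",
                                  exact = FALSE, continuity = TRUE))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-6)
})

test_that("coupling analysis matches a manual rank regression and handles exclusions", {
  set.seed(64)
  inj <- recovery_injections()
  cfg <- scenario_config(injected_events = inj, coupling_beta = 0.8, seed = 9)
  scen <- generate_scenario(cfg)
  clim <- build_climatology(scen$temperature)
  ev <- detect_events(scen$temperature, clim)
  summ <- cohort_cumulative(ev, scen$temperature, clim)
  weekly <- compute_weekly_cpue(scen$records)

  cp <- coupling_analysis(summ, weekly)
  ser <- weekly_series(weekly, "TOTAL")
  wcl <- build_climatology(ser)
  bio <- cohort_cumulative(ser, wcl, cohorts = summ$cohort_year)
  manual <- rank_regression(rank_cohorts(summ), rank_cohorts(bio))
  expect_equal(cp$slope, manual$slope)
  expect_equal(cp$p_value, manual$p_value)

  # empty exclusion is a no-op; excluding everything is an error
  cp0 <- coupling_analysis(summ, weekly, exclude_groups = character())
  expect_equal(cp0$slope, cp$slope)
  expect_error(coupling_analysis(summ, weekly,
                                 exclude_groups = unique(weekly$group)),
               "empty community")

  # excluded groups change the rebuilt total series
  ser_nj <- weekly_series(weekly, "TOTAL", exclude_groups = "jellyfish")
  jf <- weekly_series(weekly, "jellyfish")
  both <- !is.na(ser$values) & !is.na(jf$values)
  expect_equal(ser_nj$values[both], (ser$values - jf$values)[both])
})
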