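# Fixtures build on a flat series whose climatology collapses to
# mean = lower = upper = 5, so exceedances are fully controlled.
make_flat <- function() {
  s <- flat_series(5)
  cl <- build_climatology(s, smooth_span = 0)  # exact collapsed envelope
  list(s = s, cl = cl)
}

bump <- function(s, start, len, by) {
  i <- match(as.Date(start), s$dates)
  s$values[i:(i + len - 1)] <- s$values[i:(i + len - 1)] + by
  s
}

test_that("series inside the envelope yield no events", {
  fx <- make_flat()
  ev <- detect_events(fx$s, fx$cl)  # constant = never strictly outside
  expect_equal(nrow(ev), 0L)
})

test_that("runs at or above the minimum duration become events, shorter ones do not", {
  fx <- make_flat()
  s8 <- bump(fx$s, "2013-06-01", 8, 1)
  ev <- detect_events(s8, fx$cl, min_duration = 5, max_gap = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$sign, "positive")
  expect_equal(ev$duration, 8L)
  expect_equal(ev$start, as.Date("2013-06-01"))

  s4 <- bump(fx$s, "2013-06-01", 4, 1)
  expect_equal(nrow(detect_events(s4, fx$cl, min_duration = 5)), 0L)
  # the strict more-than-five-days reading is available
  s5 <- bump(fx$s, "2013-06-01", 5, 1)
  expect_equal(nrow(detect_events(s5, fx$cl, min_duration = 6)), 0L)
  expect_equal(nrow(detect_events(s5, fx$cl, min_duration = 5)), 1L)
})

test_that("day-degree metrics sum daily departures from the chosen baseline", {
  fx <- make_flat()
  s <- bump(fx$s, "2013-06-01", 5, 1)
  expect_equal(event_day_degrees(s, fx$cl, "2013-06-01", "2013-06-05",
                                 sign = "positive", baseline = "mean"), 5)
  # cold event mean-2, mean-1, mean-3
  sc <- fx$s
  i <- match(as.Date("2014-02-01"), sc$dates)
  sc$values[i:(i + 2)] <- sc$values[i:(i + 2)] - c(2, 1, 3)
  expect_equal(event_day_degrees(sc, fx$cl, "2014-02-01", "2014-02-03",
                                 sign = "negative", baseline = "mean"), -6)
  # values exactly on the threshold contribute zero against it
  expect_equal(event_day_degrees(fx$s, fx$cl, "2013-06-01", "2013-06-05",
                                 sign = "positive", baseline = "threshold"), 0)
  expect_error(event_day_degrees(s, fx$cl, "2011-01-01", "2011-01-05",
                                 sign = "positive"), "outside")
})

test_that("net daily anomalies are the signed exceedance on event days only", {
  fx <- make_flat()
  ev0 <- detect_events(fx$s, fx$cl)
  net0 <- net_daily_anomaly(fx$s, fx$cl, ev0)
  expect_true(all(net0$values == 0))

  s <- bump(fx$s, "2013-06-01", 6, 0.7)
  ev <- detect_events(s, fx$cl)
  net <- net_daily_anomaly(s, fx$cl, ev)
  i <- match(as.Date("2013-06-01"), s$dates)
  expect_equal(net$values[i], 0.7)
  expect_equal(sum(net$values != 0), 6L)
  # cross-operation consistency with the threshold-baseline day-degrees
  expect_equal(sum(net$values),
               event_day_degrees(s, fx$cl, ev$start[1], ev$end[1],
                                 sign = "positive", baseline = "threshold"))
  expect_equal(sum(net$values), ev$day_degrees_threshold[1])
})

test_that("missing days terminate runs and never count toward gaps", {
  fx <- make_flat()
  s <- bump(fx$s, "2013-06-01", 12, 1)
  i <- match(as.Date("2013-06-06"), s$dates)
  s$values[i] <- NA
  ev <- detect_events(s, fx$cl, min_duration = 5, max_gap = 2)
  expect_equal(nrow(ev), 2L)  # the NA splits despite max_gap = 2
  expect_equal(ev$duration, c(5L, 6L))
})

test_that("gap joining merges same-sign runs across short inside-envelope gaps", {
  fx <- make_flat()
  s <- bump(fx$s, "2013-06-01", 4, 1)
  s <- bump(s, "2013-06-06", 4, 1)    # one inside-envelope day between
  expect_equal(nrow(detect_events(s, fx$cl, min_duration = 5, max_gap = 0)), 0L)
  ev <- detect_events(s, fx$cl, min_duration = 5, max_gap = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 9L)
  # opposite-sign neighbours never merge
  s2 <- bump(fx$s, "2013-06-01", 6, 1)
  s2 <- bump(s2, "2013-06-07", 6, -1)
  ev2 <- detect_events(s2, fx$cl, min_duration = 5, max_gap = 2)
  expect_equal(ev2$sign, c("positive", "negative"))
})

test_that("detection matches the brute-force linear scan on random series", {
  set.seed(41)
  fx <- make_flat()
  upper <- rep(5, length(fx$s$dates))
  for (rep_i in 1:300) {
    n <- sample(20:60, 1)
    vals <- 5 + sample(c(-1, 0, 1), n, replace = TRUE) *
      round(runif(n, 0, 2), 2)
    vals[runif(n) < 0.1] <- NA
    s <- daily_series(fx$s$dates[1:n], vals, variable = "temperature")
    md <- sample(1:5, 1)
    ev <- detect_events(s, fx$cl, min_duration = md, max_gap = 0)
    bf <- bf_detect(vals, upper[1:n], upper[1:n], md)
    expect_equal(nrow(ev), nrow(bf))
    if (nrow(bf) > 0) {
      expect_equal(ev$start, s$dates[bf$start])
      expect_equal(ev$end, s$dates[bf$end])
      expect_equal(ev$sign, ifelse(bf$sign > 0, "positive", "negative"))
    }
  }
})

test_that("events never overlap, sign is consistent, and min_duration is monotone", {
  set.seed(42)
  fx <- make_flat()
  for (rep_i in 1:50) {
    n <- 120
    vals <- 5 + cumsum(rnorm(n, 0, 0.6))
    s <- daily_series(fx$s$dates[1:n], vals, variable = "temperature")
    u <- fjordwave:::aligned_doy(s$dates)
    ev <- detect_events(s, fx$cl, min_duration = 3, max_gap = 0)
    if (nrow(ev) > 1) {
      all_days <- do.call(c, lapply(seq_len(nrow(ev)), function(i)
        seq(ev$start[i], ev$end[i], by = "day")))
      expect_equal(anyDuplicated(all_days), 0L)
    }
    for (i in seq_len(nrow(ev))) {
      idx <- match(seq(ev$start[i], ev$end[i], by = "day"), s$dates)
      if (ev$sign[i] == "positive")
        expect_true(all(vals[idx] > fx$cl$upper[u[idx]]))
      else
        expect_true(all(vals[idx] < fx$cl$lower[u[idx]]))
    }
    n_by_dur <- sapply(1:8, function(md)
      nrow(detect_events(s, fx$cl, min_duration = md)))
    expect_true(all(diff(n_by_dur) <= 0))
  }
})
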