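# Independent brute-force oracles and fixture builders used across tests.

# Linear-scan event detector (max_gap = 0 semantics): returns a data.frame
# of runs where value strictly exceeds the envelope for >= min_duration
# consecutive non-missing days.
bf_detect <- function(values, upper, lower, min_duration) {
  n <- length(values)
  out <- list()
  i <- 1L
  while (i <= n) {
    v <- values[i]
    s <- if (!is.na(v) && v > upper[i]) 1L
         else if (!is.na(v) && v < lower[i]) -1L else 0L
    if (s == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n) {
      w <- values[j + 1L]
      nxt <- if (is.na(w)) 0L else if (w > upper[j + 1L]) 1L
             else if (w < lower[j + 1L]) -1L else 0L
      if (nxt != s) break
      j <- j + 1L
    }
    if (j - i + 1L >= min_duration)
      out[[length(out) + 1L]] <- data.frame(sign = s, start = i, end = j)
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(sign = integer(), start = integer(), end = integer()))
  do.call(rbind, out)
}

# Exhaustive pair enumeration for the Mann-Kendall S statistic.
bf_mk_s <- function(x) {
  s <- 0L
  n <- length(x)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      s <- s + sign(x[j] - x[i])
  as.integer(s)
}

# Series constant at `level` except that 15 March of ten successive years
# carries the values 1..10: that unit's single-day pool is exactly {1..10}.
percentile_fixture <- function(level = 5) {
  all_days <- seq(as.Date("2001-01-01"), as.Date("2010-12-31"), by = "day")
  vals <- rep(level, length(all_days))
  vals[match(as.Date(sprintf("%d-03-15", 2001:2010)), all_days)] <- 1:10
  daily_series(all_days, vals, variable = "temperature")
}

# Per-week threshold filter followed by same-sign run merging: the
# brute-force counterpart of detect_biotic_anomalies (adjacent rows only).
bf_biotic <- function(values, upper, lower) {
  s <- ifelse(is.na(values), 0L,
              ifelse(values > upper, 1L, ifelse(values < lower, -1L, 0L)))
  out <- list()
  i <- 1L
  while (i <= length(s)) {
    if (s[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
    ex <- if (s[i] > 0) values[i:j] - upper[i:j] else values[i:j] - lower[i:j]
    out[[length(out) + 1L]] <- data.frame(sign = s[i], start = i, end = j,
                                          magnitude = sum(ex))
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(sign = integer(), start = integer(), end = integer(),
                      magnitude = numeric()))
  do.call(rbind, out)
}

# A flat multi-year daily series whose climatology is trivially constant,
# convenient for constructing exact exceedance fixtures.
flat_series <- function(level = 5, start = "2012-01-01", end = "2015-12-31",
                        variable = "temperature") {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  daily_series(dates, rep(level, length(dates)), variable = variable)
}

# Injected-event set giving eight cohort years distinct net day-degrees
# (four warm-dominated, four cold-dominated), used by the end-to-end
# recovery checks.
recovery_injections <- function() {
  amps <- c(2.5, 2.0, -2.4, 2.8, -1.8, 2.2, -2.6, -2.1)
  lapply(seq_along(amps), function(i)
    list(variable = "temperature", start = sprintf("%d-01-10", 2012 + i),
         duration = 20 + 2 * i, amplitude = amps[i]))
}

# One full synthetic pipeline pass: generate, detect temperature events,
# aggregate cohorts, standardize CPUE and fit the community coupling.
pipeline_coupling <- function(seed, beta, injections = recovery_injections()) {
  cfg <- scenario_config(injected_events = injections, coupling_beta = beta,
                         seed = seed)
  scen <- generate_scenario(cfg)
  clim <- build_climatology(scen$temperature)
  ev <- detect_events(scen$temperature, clim)
  summ <- cohort_cumulative(ev, scen$temperature, clim)
  weekly <- compute_weekly_cpue(scen$records)
  coupling_analysis(summ, weekly)
}

# Jaccard overlap between detected and injected event day-sets.
event_day_jaccard <- function(events, truth_events) {
  days_of <- function(st, en) {
    if (length(st) == 0L) return(as.Date(character()))
    do.call(c, lapply(seq_along(st), function(i) seq(st[i], en[i], by = "day")))
  }
  det <- days_of(events$start, events$end)
  inj <- days_of(truth_events$start, truth_events$end)
  if (length(det) == 0L && length(inj) == 0L) return(1)
  length(intersect(det, inj)) / length(union(det, inj))
}
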