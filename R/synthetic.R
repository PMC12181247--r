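#' Default biotic group layout for synthetic scenarios
#'
#' Eight groups with winter-peaked seasonal profiles (peak weeks counted on
#' the 01-August-anchored grid, so weeks 16-26 fall in the polar winter)
#' and peak CPUE levels on the order of the weekly abundances of a polar
#' fjord shallow-water community.
#'
#' @param concentration breadth of the seasonal bump (larger is narrower).
#' @return `data.frame` with columns `group`, `peak_week`, `peak_cpue`,
#'   `concentration`.
#' @export
default_biota_groups <- function(concentration = 2) {
  data.frame(
    group = c("appendicularia", "benthic_crustacea", "chaetognatha", "fish",
              "jellyfish", "pelagic_crustacea", "pteropoda", "others"),
    peak_week = c(16, 24, 20, 22, 14, 26, 18, 22),
    peak_cpue = c(15, 38, 11, 27, 19, 29, 13, 1.5),
    concentration = concentration
  )
}

#' Scenario configuration for the synthetic observatory generator
#'
#' Defines an emulated multi-year observatory record: seasonal sinusoids
#' for temperature (summer-warm) and salinity (winter-high) with AR(1)
#' daily noise, injected warm/cold and high-/low-salinity events of known
#' timing and amplitude, and weekly survey counts with winter-peaked
#' seasonal profiles, gamma-mixed (negative binomial) overdispersion and a
#' configurable coupling of expected CPUE to cohort-level temperature
#' anomaly day-degrees.
#'
#' @param start,end span of the record (dates). The default covers eight
#'   full cohort years, 2012-08-01 through 2020-07-31.
#' @param temp_mean,temp_amplitude,temp_phase annual mean (deg C), seasonal
#'   half-amplitude (deg C) and aligned day-of-year of the seasonal
#'   maximum. Defaults 3, 3.5 and 220 (early August maximum).
#' @param temp_ar1,temp_noise_sd AR(1) coefficient in `[0, 1)` and
#'   stationary standard deviation (deg C) of the daily noise.
#' @param sal_mean,sal_amplitude,sal_phase,sal_ar1,sal_noise_sd salinity
#'   analogues (PSU); the default phase 50 puts the maximum in late winter.
#' @param injected_events list of events, each a list with fields
#'   `variable` (`"temperature"` or `"salinity"`), `start` (date),
#'   `duration` (days) and `amplitude` (signed, variable units). Events of
#'   one variable must not overlap.
#' @param biota group table as from [default_biota_groups()].
#' @param dispersion negative binomial size parameter (> 0); `Inf` gives
#'   Poisson counts.
#' @param coupling_beta effect of the standardized cohort net day-degrees
#'   of injected temperature events on log expected CPUE.
#' @param effort_dropout probability that a week's analysed effort drops
#'   below the nominal 336 image pairs.
#' @param seed master seed; split into independent sub-streams per variable
#'   and group so adding a group leaves other streams untouched.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(start = "2012-08-01", end = "2020-07-31",
                            temp_mean = 3, temp_amplitude = 3.5,
                            temp_phase = 220, temp_ar1 = 0.7,
                            temp_noise_sd = 0.5,
                            sal_mean = 34, sal_amplitude = 0.8,
                            sal_phase = 50, sal_ar1 = 0.7,
                            sal_noise_sd = 0.15,
                            injected_events = list(),
                            biota = default_biota_groups(),
                            dispersion = 1.5, coupling_beta = 0,
                            effort_dropout = 0.1, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("end must be after start")
  stopifnot(temp_amplitude >= 0, sal_amplitude >= 0, dispersion > 0,
            temp_ar1 >= 0, temp_ar1 < 1, sal_ar1 >= 0, sal_ar1 < 1,
            effort_dropout >= 0, effort_dropout <= 1)
  structure(
    list(start = start, end = end,
         temperature = list(mean = temp_mean, amplitude = temp_amplitude,
                            phase = temp_phase, ar1 = temp_ar1,
                            noise_sd = temp_noise_sd),
         salinity = list(mean = sal_mean, amplitude = sal_amplitude,
                         phase = sal_phase, ar1 = sal_ar1,
                         noise_sd = sal_noise_sd),
         injected_events = injected_events, biota = biota,
         dispersion = dispersion, coupling_beta = coupling_beta,
         effort_dropout = effort_dropout, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Seasonal curve on the aligned 366-day frame, identical across years.
seasonal_curve <- function(dates, pars) {
  doy <- aligned_doy(dates)
  pars$mean + pars$amplitude * cos(2 * pi * (doy - pars$phase) / 366)
}

#' Generate synthetic daily temperature and salinity series
#'
#' Each variable is `seasonal sinusoid + AR(1) noise + injected event
#' boxcars`. With `noise_sd = 0` the series is exactly the sinusoid plus
#' injections. The same seed always yields identical output.
#'
#' @param config a [scenario_config()].
#' @return list with elements `temperature` and `salinity` (both
#'   [daily_series()]) and `truth`: the injected-event table and the
#'   per-cohort net day-degrees of injected temperature and salinity
#'   events (the designed ground truth driving any biotic coupling).
#' @export
generate_abiotic <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  dates <- seq(config$start, config$end, by = "day")
  n <- length(dates)
  out <- list()
  for (vn in c("temperature", "salinity")) {
    pars <- config[[vn]]
    vals <- seasonal_curve(dates, pars)
    if (pars$noise_sd > 0) {
      set.seed(substream_seed(config$seed, vn))
      innov_sd <- pars$noise_sd * sqrt(1 - pars$ar1^2)
      e <- numeric(n)
      eps <- stats::rnorm(n, 0, innov_sd)
      e[1] <- stats::rnorm(1, 0, pars$noise_sd)
      for (t in 2:n) e[t] <- pars$ar1 * e[t - 1] + eps[t]
      vals <- vals + e
    }
    ev <- Filter(function(x) identical(x$variable, vn), config$injected_events)
    if (length(ev) > 0) {
      windows <- lapply(ev, function(x) {
        s <- as.Date(x$start); seq(s, s + x$duration - 1, by = "day")
      })
      all_days <- do.call(c, windows)
      if (anyDuplicated(all_days))
        stop("overlapping injected events for ", vn)
      for (j in seq_along(ev))
        vals[dates %in% windows[[j]]] <- vals[dates %in% windows[[j]]] +
          ev[[j]]$amplitude
    }
    out[[vn]] <- daily_series(dates, vals, variable = vn)
  }
  ev_df <- if (length(config$injected_events) > 0)
    do.call(rbind, lapply(config$injected_events, function(x)
      data.frame(variable = x$variable,
                 sign = if (x$amplitude >= 0) "positive" else "negative",
                 start = as.Date(x$start),
                 end = as.Date(x$start) + x$duration - 1,
                 duration = as.integer(x$duration),
                 amplitude = x$amplitude,
                 day_degrees = x$amplitude * x$duration)))
  else
    data.frame(variable = character(), sign = character(),
               start = as.Date(character()), end = as.Date(character()),
               duration = integer(), amplitude = numeric(),
               day_degrees = numeric())
  cohorts <- seq(assign_cohort_year(config$start),
                 assign_cohort_year(config$end))
  dd <- expand.grid(cohort_year = cohorts,
                    variable = c("temperature", "salinity"),
                    stringsAsFactors = FALSE)
  dd$net_day_degrees <- 0
  for (i in seq_len(nrow(ev_df))) {
    days <- seq(ev_df$start[i], ev_df$end[i], by = "day")
    ch <- assign_cohort_year(days)
    for (y in unique(ch)) {
      sel <- dd$cohort_year == y & dd$variable == ev_df$variable[i]
      dd$net_day_degrees[sel] <- dd$net_day_degrees[sel] +
        ev_df$amplitude[i] * sum(ch == y)
    }
  }
  list(temperature = out$temperature, salinity = out$salinity,
       truth = list(events = ev_df, cohort_net_day_degrees = dd,
                    config = config))
}

#' Generate synthetic weekly survey records
#'
#' Weekly counts per biotic group on the 01-August-anchored grid. Expected
#' CPUE is `peak_cpue x seasonal profile x exp(coupling_beta x z)`, where
#' `z` is the standardized per-cohort net day-degrees of the injected
#' temperature events (cumulative exposure, not instantaneous temperature,
#' drives the response). Counts are negative binomial (gamma-mixed Poisson)
#' with the configured dispersion, scaled by realized effort; effort is 336
#' image pairs unless dropout reduces it.
#'
#' @param config a [scenario_config()].
#' @param truth the `truth` element of [generate_abiotic()] (for the
#'   cohort day-degree driver).
#' @return `data.frame` of survey records (`week_start`, `image_pairs`,
#'   one column per group) with attribute `expected`: the true expected
#'   CPUE per group and week.
#' @export
generate_biota <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  cohorts <- seq(assign_cohort_year(config$start),
                 assign_cohort_year(config$end))
  week_starts <- do.call(c, lapply(cohorts, function(y)
    as.Date(sprintf("%d-08-01", y)) + 7 * (0:51)))
  week_starts <- week_starts[week_starts >= config$start &
                             week_starts <= config$end]
  nw <- length(week_starts)

  dd <- truth$cohort_net_day_degrees
  dd <- dd[dd$variable == "temperature", ]
  z <- if (stats::sd(dd$net_day_degrees) > 0)
    as.numeric(scale(dd$net_day_degrees)) else rep(0, nrow(dd))
  zw <- z[match(assign_cohort_year(week_starts), dd$cohort_year)]

  set.seed(substream_seed(config$seed, "effort"))
  drop <- stats::runif(nw) < config$effort_dropout
  effort <- rep(336L, nw)
  effort[drop] <- sample(48:335, sum(drop), replace = TRUE)

  wk <- cohort_week(week_starts)
  records <- data.frame(week_start = week_starts, image_pairs = effort)
  expected <- data.frame(week_start = week_starts)
  for (i in seq_len(nrow(config$biota))) {
    g <- config$biota$group[i]
    profile <- exp(config$biota$concentration[i] *
                   (cos(2 * pi * (wk - config$biota$peak_week[i]) / 52) - 1))
    mu_cpue <- config$biota$peak_cpue[i] * profile *
      exp(config$coupling_beta * zw)
    set.seed(substream_seed(config$seed, paste0("group_", g)))
    mu_count <- mu_cpue * effort / 336
    counts <- if (is.finite(config$dispersion))
      stats::rnbinom(nw, mu = mu_count, size = config$dispersion)
    else stats::rpois(nw, mu_count)
    records[[g]] <- counts
    expected[[g]] <- mu_cpue
  }
  attr(records, "expected") <- expected
  class(records) <- c("survey_records", "data.frame")
  records
}

#' Generate a complete synthetic scenario
#'
#' Runs [generate_abiotic()] and [generate_biota()] for one configuration.
#'
#' @param config a [scenario_config()].
#' @return list with `temperature`, `salinity`, `records` and `truth`.
#' @export
generate_scenario <- function(config) {
  ab <- generate_abiotic(config)
  records <- generate_biota(config, ab$truth)
  list(temperature = ab$temperature, salinity = ab$salinity,
       records = records, truth = ab$truth)
}
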