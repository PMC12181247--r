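#' Detect anomaly events against a climatological envelope
#'
#' A positive run is a maximal block of consecutive days whose value lies
#' strictly above the upper envelope curve (a heat wave or high-salinity
#' phase); a negative run lies strictly below the lower curve (cold spell,
#' low-salinity phase). Runs of equal sign separated by at most `max_gap`
#' inside-envelope, non-missing days are merged; missing days always break
#' runs and never count toward gaps. Runs whose total duration (gap days
#' included) reaches `min_duration` become events.
#'
#' @param series a daily [daily_series()].
#' @param clim a matching [build_climatology()] table (day-of-year keyed).
#' @param min_duration minimum event duration in days. Default 5, the
#'   conventional marine-heat-wave minimum; set 6 for a strict
#'   more-than-five-days reading.
#' @param max_gap maximum number of inside-envelope days bridged between
#'   same-sign runs. Default 0 (strictly continuous exceedance); 2 gives
#'   the gap-joining variant common in heat-wave climatologies.
#' @return a `data.frame` of class `anomaly_events`, date-ordered and
#'   non-overlapping, with columns `variable`, `sign` (`"positive"` /
#'   `"negative"`), `start`, `end`, `duration`,
#'   `day_degrees_mean` (intensity summed against the climatological mean,
#'   signed unit-days), `day_degrees_threshold` (summed against the crossed
#'   envelope curve) and `max_exceedance` (peak daily excursion beyond the
#'   crossed curve, signed).
#' @export
detect_events <- function(series, clim, min_duration = 5L, max_gap = 0L) {
  stopifnot(inherits(series, "daily_series"), inherits(clim, "climatology_table"))
  if (min_duration < 1L) stop("min_duration must be >= 1")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  u <- clim_units(clim, series)
  v <- series$values
  upper <- clim$upper[u]; lower <- clim$lower[u]

  state <- integer(length(v))            # +1 above, -1 below, 0 inside
  state[!is.na(v) & v > upper] <- 1L
  state[!is.na(v) & v < lower] <- -1L
  state[is.na(v)] <- 9L                  # missing: breaks runs, never a gap

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(value = r$values, start = starts, end = ends)

  # merge same-sign candidate runs across short inside-envelope gaps
  merged <- list()
  for (i in seq_len(nrow(runs))) {
    rv <- runs$value[i]
    if (rv != 1L && rv != -1L) next
    k <- length(merged)
    if (k > 0L) {
      prev <- merged[[k]]
      gap_len <- runs$start[i] - prev$end - 1L
      gap_idx <- if (gap_len > 0L) (prev$end + 1L):(runs$start[i] - 1L) else integer(0)
      gap_ok <- gap_len <= max_gap && all(state[gap_idx] == 0L)
      if (prev$sign == rv && gap_ok) {
        merged[[k]]$end <- runs$end[i]
        next
      }
    }
    merged[[k + 1L]] <- list(sign = rv, start = runs$start[i], end = runs$end[i])
  }

  rows <- lapply(merged, function(ev) {
    dur <- ev$end - ev$start + 1L
    if (dur < min_duration) return(NULL)
    idx <- ev$start:ev$end
    thr <- if (ev$sign > 0L) upper[idx] else lower[idx]
    exceed <- v[idx] - thr
    data.frame(
      variable = series$variable,
      sign = if (ev$sign > 0L) "positive" else "negative",
      start = series$dates[ev$start],
      end = series$dates[ev$end],
      duration = dur,
      day_degrees_mean = sum(v[idx] - clim$mean[u[idx]]),
      day_degrees_threshold = sum(exceed),
      max_exceedance = if (ev$sign > 0L) max(exceed) else min(exceed)
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(variable = character(), sign = character(),
                      start = as.Date(character()), end = as.Date(character()),
                      duration = integer(), day_degrees_mean = numeric(),
                      day_degrees_threshold = numeric(),
                      max_exceedance = numeric())
  class(out) <- c("anomaly_events", "data.frame")
  attr(out, "variable") <- series$variable
  out
}

#' Cumulative day-degrees of an event window
#'
#' Sums the daily departure of the series from a baseline curve over a
#' detected event's days: `duration x intensity` in variable-unit days,
#' signed. The baseline is either the climatological mean (the usual
#' heat-wave intensity convention) or the crossed percentile threshold (the
#' net-anomalous-value convention).
#'
#' @param series,clim the series and climatology the event was detected in.
#' @param start,end event start and end dates.
#' @param sign `"positive"` or `"negative"` (selects the crossed curve for
#'   the threshold baseline).
#' @param baseline `"mean"` or `"threshold"`.
#' @return signed day-degrees (numeric scalar).
#' @export
event_day_degrees <- function(series, clim, start, end,
                              sign = c("positive", "negative"),
                              baseline = c("mean", "threshold")) {
  sign <- match.arg(sign)
  baseline <- match.arg(baseline)
  start <- as.Date(start); end <- as.Date(end)
  idx <- match(seq(start, end, by = "day"), series$dates)
  if (anyNA(idx)) stop("event days fall outside the series")
  if (anyNA(series$values[idx])) stop("event days include missing values")
  u <- clim_units(clim, series)[idx]
  base <- switch(baseline,
                 mean = clim$mean[u],
                 threshold = if (sign == "positive") clim$upper[u] else clim$lower[u])
  sum(series$values[idx] - base)
}

#' Net daily anomalous values
#'
#' The signed daily exceedance beyond the crossed envelope curve -- value
#' minus upper curve above it, value minus lower curve below it -- reported
#' only on days belonging to a detected event and zero everywhere else.
#'
#' @param series,clim the series and climatology used for detection.
#' @param events the [detect_events()] result.
#' @return a [daily_series()] on the same dates.
#' @export
net_daily_anomaly <- function(series, clim, events) {
  u <- clim_units(clim, series)
  v <- series$values
  net <- numeric(length(v))
  for (i in seq_len(nrow(events))) {
    idx <- match(seq(events$start[i], events$end[i], by = "day"), series$dates)
    thr <- if (events$sign[i] == "positive") clim$upper[u[idx]] else clim$lower[u[idx]]
    exceed <- v[idx] - thr
    # gap-bridged inside-envelope days contribute zero, not a signed excess
    if (events$sign[i] == "positive") exceed[exceed < 0] <- 0
    else exceed[exceed > 0] <- 0
    net[idx] <- exceed
  }
  daily_series(series$dates, net, coverage = series$coverage,
               variable = paste0(series$variable, "_net_anomaly"),
               freq = series$freq)
}
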