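#' Build a per-calendar-unit percentile climatology
#'
#' For every unit of the calendar cycle (366 aligned days of year for daily
#' series, 52 anchored weeks for weekly series) the long-term mean and a
#' lower/upper percentile envelope are computed from all non-missing values
#' whose unit lies within `window_halfwidth` units of the target unit,
#' pooled across years. The three curves can then be smoothed by a circular
#' moving average. The envelope is periodic: pooling windows and smoothing
#' wrap around the end of the cycle.
#'
#' Percentiles use sorting with linear interpolation between order
#' statistics ([stats::quantile()] type 7 by default); with the small
#' number of contributing years typical of coastal observatories the
#' estimator choice is material, so it is configurable and recorded in the
#' result's `params`.
#'
#' @param series a [daily_series()] spanning at least `min_years` distinct
#'   years (cohort years for weekly series).
#' @param window_halfwidth pooling half-window in calendar units. Default 5
#'   days for daily series (an 11-day pooling window) and 1 week for weekly
#'   series.
#' @param smooth_span circular moving-average span in units applied to all
#'   three curves; `0` or `1` disables smoothing. Default 31 days for daily
#'   series, 0 for weekly.
#' @param percentile_pair lower and upper envelope fractions,
#'   `0 < low < high < 1`. Default `c(0.1, 0.9)`: the 10th and 90th
#'   percentiles conventionally used to delimit marine heat waves and cold
#'   spells.
#' @param min_years minimum number of distinct contributing years.
#' @param quantile_type percentile estimator type passed to
#'   [stats::quantile()].
#' @return an object of class `climatology_table` with fields `unit`
#'   (`"doy"` or `"week"`), `mean`, `lower`, `upper`, `n_years` (one entry
#'   per calendar unit) and `params`.
#' @export
build_climatology <- function(series, window_halfwidth = NULL,
                              smooth_span = NULL,
                              percentile_pair = c(0.1, 0.9),
                              min_years = 2L, quantile_type = 7L) {
  stopifnot(inherits(series, "daily_series"))
  weekly <- identical(series$freq, "weekly")
  unit_type <- if (weekly) "week" else "doy"
  n_units <- if (weekly) 52L else 366L
  if (is.null(window_halfwidth)) window_halfwidth <- if (weekly) 1L else 5L
  if (is.null(smooth_span)) smooth_span <- if (weekly) 0L else 31L
  if (window_halfwidth < 0) stop("window_halfwidth must be >= 0")
  lo <- percentile_pair[1]; hi <- percentile_pair[2]
  if (!(lo > 0 && lo < hi && hi < 1))
    stop("percentile_pair must satisfy 0 < low < high < 1")

  units <- if (weekly) cohort_week(series$dates) else aligned_doy(series$dates)
  yrs <- if (weekly) assign_cohort_year(series$dates)
         else as.POSIXlt(series$dates)$year + 1900L
  ok <- !is.na(series$values)
  if (length(unique(yrs[ok])) < min_years)
    stop("series contains fewer than ", min_years, " years of data")

  # bucket values (and contributing years) by unit once, then pool windows
  fu <- factor(units[ok], levels = seq_len(n_units))
  val_by_unit <- split(series$values[ok], fu)
  yr_by_unit <- split(yrs[ok], fu)

  m <- low <- up <- numeric(n_units)
  ny <- integer(n_units)
  hw <- as.integer(window_halfwidth)
  for (u in seq_len(n_units)) {
    members <- ((u - 1L - hw):(u - 1L + hw)) %% n_units + 1L
    pool <- unlist(val_by_unit[members], use.names = FALSE)
    if (length(pool) == 0L)
      stop("empty climatology pool for unit ", u,
           "; widen window_halfwidth or supply more data")
    m[u] <- mean(pool)
    qs <- stats::quantile(pool, c(lo, hi), type = quantile_type, names = FALSE)
    low[u] <- qs[1]; up[u] <- qs[2]
    ny[u] <- length(unique(unlist(yr_by_unit[members], use.names = FALSE)))
  }
  if (smooth_span > 1) {
    m <- circ_ma(m, smooth_span)
    low <- circ_ma(low, smooth_span)
    up <- circ_ma(up, smooth_span)
  }
  structure(
    list(unit = unit_type, n_units = n_units, mean = m, lower = low,
         upper = up, n_years = ny,
         params = list(window_halfwidth = hw, smooth_span = smooth_span,
                       percentile_pair = c(lo, hi), min_years = min_years,
                       quantile_type = quantile_type,
                       variable = series$variable)),
    class = "climatology_table"
  )
}

#' @export
print.climatology_table <- function(x, ...) {
  cat(sprintf("<climatology: %s, %d %s units>\n",
              x$params$variable %||% "?", x$n_units, x$unit))
  cat(sprintf("  envelope: %g-%g percentiles, window +/-%d, smooth %d\n",
              x$params$percentile_pair[1], x$params$percentile_pair[2],
              x$params$window_halfwidth, x$params$smooth_span))
  invisible(x)
}

#' @export
as.data.frame.climatology_table <- function(x, ...) {
  data.frame(unit = seq_len(x$n_units), mean = x$mean, lower = x$lower,
             upper = x$upper, n_years = x$n_years)
}

# Map series dates onto climatology units; errors on keying mismatch.
clim_units <- function(clim, series) {
  weekly <- identical(series$freq, "weekly")
  if (weekly != identical(clim$unit, "week"))
    stop("series frequency (", series$freq,
         ") does not match climatology keying (", clim$unit, ")")
  if (weekly) cohort_week(series$dates) else aligned_doy(series$dates)
}
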