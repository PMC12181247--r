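# Internal calendar helpers shared across modules.

# Day-of-year on a fixed 366-day frame: in non-leap years every date from
# 1 March onward is shifted by +1 so that a given calendar date always maps
# to the same unit (unit 60 is 29 February, unit 61 is always 1 March).
aligned_doy <- function(dates) {
  lt <- as.POSIXlt(as.Date(dates))
  doy <- lt$yday + 1L
  yr <- lt$year + 1900L
  leap <- (yr %% 4L == 0L & yr %% 100L != 0L) | yr %% 400L == 0L
  shift <- !leap & doy >= 60L
  doy[shift] <- doy[shift] + 1L
  doy
}

#' Assign calendar dates to polar cohort years
#'
#' A cohort year `Y` spans 01 August of year `Y` through 31 July of year
#' `Y + 1`, following the polar biological cycle in which shallow-water
#' abundance builds from the polar summer through the polar winter.
#'
#' @param dates a `Date` vector (or anything coercible with [as.Date()]).
#' @return integer vector of cohort-year labels.
#' @examples
#' assign_cohort_year(as.Date(c("2014-08-01", "2015-07-31", "2015-08-01")))
#' @export
assign_cohort_year <- function(dates) {
  lt <- as.POSIXlt(as.Date(dates))
  y <- lt$year + 1900L
  y[lt$mon < 7L] <- y[lt$mon < 7L] - 1L  # $mon is 0-based; August is 7
  y
}

#' Week-of-cohort-year index on the 01-August-anchored grid
#'
#' Weeks are 7-day blocks counted from 01 August of the date's cohort year.
#' The grid has 52 units; the final week absorbs the one or two remainder
#' days of the cohort year so every date maps to a unit.
#'
#' @param dates a `Date` vector.
#' @return integer week index in `1:52`.
#' @export
cohort_week <- function(dates) {
  dates <- as.Date(dates)
  y <- assign_cohort_year(dates)
  anchor <- as.Date(sprintf("%d-08-01", y))
  w <- as.integer(floor(as.numeric(dates - anchor) / 7)) + 1L
  pmin(w, 52L)
}

# Start date of the anchored week containing each date.
cohort_week_start <- function(dates) {
  dates <- as.Date(dates)
  y <- assign_cohort_year(dates)
  anchor <- as.Date(sprintf("%d-08-01", y))
  anchor + 7 * (cohort_week(dates) - 1L)
}

# Circular moving average used to smooth climatology curves. `span` is
# forced odd; span <= 1 is a no-op.
circ_ma <- function(x, span) {
  span <- as.integer(span)
  if (span <= 1L) return(x)
  if (span %% 2L == 0L) span <- span + 1L
  n <- length(x)
  k <- span %/% 2L
  stopifnot(k < n)
  xx <- c(x[(n - k + 1L):n], x, x[1L:k])
  as.numeric(stats::filter(xx, rep(1 / span, span), sides = 2))[(k + 1L):(k + n)]
}

# Deterministic per-stream seeds derived from one master seed, so that adding
# a stream (variable or biotic group) never perturbs the draws of another.
substream_seed <- function(master, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(master) %% 2147483629 * 7919 + h * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
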