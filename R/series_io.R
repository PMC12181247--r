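#' Construct a daily (or weekly) measurement series
#'
#' The basic container used throughout the package: an ordered, gap-free
#' sequence of dates with one value per date (or per week start for weekly
#' biotic series) and a per-entry coverage fraction. Values are `NA`
#' wherever no acceptable measurement exists; dates are never dropped.
#'
#' @param dates strictly increasing `Date` vector without duplicates.
#' @param values numeric vector, `NA` for missing entries.
#' @param coverage fraction of expected raw samples present per entry, in
#'   `[0, 1]`. Defaults to 1 where `values` is non-missing, 0 otherwise.
#' @param variable label, e.g. `"temperature"` (deg C) or `"salinity"` (PSU).
#' @param freq `"daily"` or `"weekly"`; weekly series are keyed to the
#'   01-August-anchored week grid (see [cohort_week()]).
#' @return an object of class `daily_series`.
#' @export
daily_series <- function(dates, values, coverage = NULL, variable = "other",
                         freq = c("daily", "weekly")) {
  freq <- match.arg(freq)
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) != length(values))
    stop("dates and values must have equal length")
  if (length(dates) == 0L) stop("empty series")
  if (is.unsorted(dates, strictly = TRUE))
    stop("dates must be strictly increasing without duplicates")
  if (is.null(coverage)) coverage <- as.numeric(!is.na(values))
  if (length(coverage) != length(dates))
    stop("coverage must match dates in length")
  if (any(coverage < 0 | coverage > 1, na.rm = TRUE))
    stop("coverage must lie in [0, 1]")
  structure(
    list(variable = variable, dates = dates, values = values,
         coverage = coverage, freq = freq),
    class = "daily_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("<%s series: %s>\n", x$freq, x$variable))
  cat(sprintf("  %d entries, %s to %s, %d missing\n",
              length(x$dates), format(min(x$dates)), format(max(x$dates)),
              n_miss))
  invisible(x)
}

#' @export
as.data.frame.daily_series <- function(x, ...) {
  data.frame(date = x$dates, value = x$values, coverage = x$coverage)
}

#' Read raw timestamped samples from a delimited text file
#'
#' Reads a CSV of raw observatory samples (e.g. hourly or 1 Hz averages).
#' Unparseable rows -- bad timestamps or non-numeric values -- are reported
#' with their line numbers and returned in the `rejects` attribute rather
#' than silently dropped; the pipeline continues on the parseable rows.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema named list mapping the roles `timestamp` and `value` to
#'   column names in the file.
#' @param tz timezone for timestamp parsing; daily binning is by UTC
#'   calendar date by default.
#' @param sep field separator.
#' @return a `data.frame` with columns `timestamp` (`POSIXct`) and `value`,
#'   in file order, with attribute `rejects` (a `data.frame` of line numbers
#'   and reasons, possibly empty).
#' @export
read_series <- function(path, schema = list(timestamp = "timestamp", value = "value"),
                        tz = "UTC", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c(schema$timestamp, schema$value)
  if (is.null(schema$timestamp) || is.null(schema$value) ||
      !all(need %in% names(raw)))
    stop("declared columns not present in file: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0L) stop("zero parseable rows in ", path)
  ts_raw <- raw[[schema$timestamp]]
  ts <- as.POSIXct(rep(NA_real_, length(ts_raw)), tz = tz,
                   origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(ts))
    if (length(idx) == 0L) break
    ts[idx] <- as.POSIXct(strptime(ts_raw[idx], fmt, tz = tz))
  }
  val <- suppressWarnings(as.numeric(raw[[schema$value]]))
  bad_ts <- is.na(ts)
  bad_val <- !bad_ts & (is.na(val) | !is.finite(val)) &
    !(trimws(raw[[schema$value]]) %in% c("", "NA"))
  explicit_na <- !bad_ts & trimws(raw[[schema$value]]) %in% c("", "NA")
  keep <- !bad_ts & !bad_val
  rejects <- data.frame(
    line = which(!keep) + 1L,  # +1 for the header row
    reason = ifelse(bad_ts[!keep], "unparseable timestamp", "non-numeric value")
  )
  if (nrow(rejects) > 0L)
    message(nrow(rejects), " rejected row(s) in ", basename(path),
            " (lines ", paste(utils::head(rejects$line, 5L), collapse = ", "),
            if (nrow(rejects) > 5L) ", ..." else "", ")")
  out <- data.frame(timestamp = ts[keep], value = val[keep])
  out$value[explicit_na[keep]] <- NA_real_
  if (nrow(out) == 0L) stop("zero parseable rows in ", path)
  attr(out, "rejects") <- rejects
  out
}

#' Aggregate raw samples to a daily mean series
#'
#' Bins samples by UTC calendar date and averages them. Every date from the
#' first to the last sampled date is present in the result; dates whose
#' coverage (observed samples / expected samples per day) falls below
#' `min_coverage` carry a missing value, so single stray readings cannot
#' define a daily mean.
#'
#' @param samples data.frame as returned by [read_series()].
#' @param min_coverage minimum fraction of expected samples required for a
#'   daily mean to count, in `[0, 1]`. Default 0.5.
#' @param expected_per_day expected number of samples per day at the native
#'   recording frequency. Default: the maximum daily count observed.
#' @param variable label passed to the resulting series.
#' @return a [daily_series()].
#' @export
aggregate_daily <- function(samples, min_coverage = 0.5,
                            expected_per_day = NULL, variable = "other") {
  if (NROW(samples) == 0L) stop("no samples to aggregate")
  if (min_coverage < 0 || min_coverage > 1) stop("min_coverage must be in [0, 1]")
  day <- as.Date(samples$timestamp, tz = "UTC")
  ok <- !is.na(samples$value)
  all_days <- seq(min(day), max(day), by = "day")
  cnt <- table(factor(day[ok], levels = as.character(all_days)))
  cnt <- as.numeric(cnt)
  if (is.null(expected_per_day)) expected_per_day <- max(cnt, 1)
  sums <- tapply(samples$value[ok], factor(day[ok], levels = as.character(all_days)),
                 sum)
  means <- as.numeric(sums) / ifelse(cnt > 0, cnt, NA)
  coverage <- pmin(cnt / expected_per_day, 1)
  means[cnt == 0 | coverage < min_coverage] <- NA_real_
  daily_series(all_days, means, coverage, variable = variable)
}

#' Write a daily series to the canonical CSV layout
#'
#' Columns `date, value, coverage`; the inverse of [read_daily_series()].
#'
#' @param series a [daily_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a canonical daily-series CSV
#'
#' @param path path to a CSV written by [write_daily_series()].
#' @param variable label for the series.
#' @param freq `"daily"` or `"weekly"`.
#' @return a [daily_series()].
#' @export
read_daily_series <- function(path, variable = "other", freq = "daily") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_series(as.Date(d$date), d$value,
               coverage = if ("coverage" %in% names(d)) d$coverage else NULL,
               variable = variable, freq = freq)
}
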