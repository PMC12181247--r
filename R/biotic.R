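# Controlled vocabulary of biotic groups and label aliases.
fw_groups <- c("appendicularia", "benthic_crustacea", "chaetognatha", "fish",
               "jellyfish", "pelagic_crustacea", "pteropoda", "others")
fw_group_aliases <- c(scyphozoa = "jellyfish", pisces = "fish")

#' Standardize weekly survey counts to catch per unit effort
#'
#' CPUE is the organism count rescaled to the nominal weekly sampling
#' effort of 336 stereoscopic image pairs (2 image pairs per hour x 24 h x
#' 7 days): `cpue = count * nominal_effort / effort`. Weeks whose analysed
#' effort falls below `effort_floor` image pairs are marked missing rather
#' than rescaled from almost nothing. A `TOTAL` row summing all group CPUEs
#' is emitted per week.
#'
#' @param records `data.frame` with columns `week_start`, `image_pairs` and
#'   one nonnegative integer count column per biotic group. Group columns
#'   named by a known alias (e.g. `scyphozoa`) are renamed to the
#'   controlled vocabulary.
#' @param nominal_effort nominal image pairs per week. Default 336.
#' @param effort_floor minimum analysed image pairs for a week to count
#'   (default 48, one full day at one pair per half hour).
#' @param aliases named character vector mapping label aliases to canonical
#'   group labels.
#' @return long `data.frame` of class `weekly_cpue` with columns
#'   `week_start`, `group`, `count`, `effort`, `cpue`.
#' @export
compute_weekly_cpue <- function(records, nominal_effort = 336,
                                effort_floor = 48,
                                aliases = fw_group_aliases) {
  stopifnot(all(c("week_start", "image_pairs") %in% names(records)))
  records$week_start <- as.Date(records$week_start)
  if (anyDuplicated(records$week_start))
    stop("duplicate week_start rows in survey records")
  nm <- names(records)
  hit <- nm %in% names(aliases)
  nm[hit] <- aliases[nm[hit]]
  names(records) <- nm
  groups <- setdiff(names(records), c("week_start", "image_pairs"))
  if (length(groups) == 0L) stop("no group count columns found")
  if (anyDuplicated(groups)) stop("duplicate group columns after aliasing")
  counts <- as.matrix(records[groups])
  if (any(counts < 0, na.rm = TRUE)) stop("negative organism counts")
  if (any(records$image_pairs < 0)) stop("negative effort")

  eff <- records$image_pairs
  usable <- eff >= effort_floor & eff > 0
  scale <- ifelse(usable, nominal_effort / eff, NA_real_)
  cpue <- counts * scale
  total <- rowSums(counts) * scale

  out <- data.frame(
    week_start = rep(records$week_start, times = length(groups) + 1L),
    group = rep(c(groups, "TOTAL"), each = nrow(records)),
    count = c(as.vector(counts), rowSums(counts)),
    effort = rep(eff, times = length(groups) + 1L),
    cpue = c(as.vector(cpue), total)
  )
  out <- out[order(out$week_start, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("weekly_cpue", "data.frame")
  attr(out, "nominal_effort") <- nominal_effort
  attr(out, "effort_floor") <- effort_floor
  out
}

#' Extract one group's weekly CPUE as a series
#'
#' @param weekly a [compute_weekly_cpue()] table.
#' @param group a group label or `"TOTAL"`.
#' @param exclude_groups groups to drop before rebuilding the `TOTAL`
#'   series (only meaningful with `group = "TOTAL"`); totals are recomputed
#'   from the remaining groups' weekly CPUE, not by subtracting anomalies.
#' @return a weekly [daily_series()] of CPUE values.
#' @export
weekly_series <- function(weekly, group = "TOTAL", exclude_groups = character()) {
  stopifnot(inherits(weekly, "weekly_cpue"))
  if (identical(group, "TOTAL") && length(exclude_groups) > 0L) {
    all_groups <- setdiff(unique(weekly$group), "TOTAL")
    keep <- setdiff(all_groups, exclude_groups)
    if (length(keep) == 0L) stop("all groups excluded: empty community")
    sub <- weekly[weekly$group %in% keep, ]
    agg <- stats::aggregate(cpue ~ week_start, data = sub, FUN = sum,
                            na.action = stats::na.pass)
    # any missing member week makes the rebuilt total missing
    miss <- stats::aggregate(is.na(sub$cpue), by = list(week_start = sub$week_start),
                             FUN = any)
    agg$cpue[miss$x[match(agg$week_start, miss$week_start)]] <- NA_real_
    agg <- agg[order(agg$week_start), ]
    return(daily_series(agg$week_start, agg$cpue, variable = "cpue_total",
                        freq = "weekly"))
  }
  sub <- weekly[weekly$group == group, ]
  if (nrow(sub) == 0L) stop("unknown group: ", group)
  sub <- sub[order(sub$week_start), ]
  daily_series(sub$week_start, sub$cpue,
               variable = paste0("cpue_", tolower(group)), freq = "weekly")
}

#' Detect weekly biotic anomalies against a weekly climatology
#'
#' A week qualifies as anomalous when its CPUE lies strictly above the
#' upper or strictly below the lower weekly envelope. Because a full sweep
#' of the water column takes the camera system seven days, the minimum
#' anomaly duration is one week rather than the five days used for the
#' abiotic series. Consecutive qualifying weeks of equal sign merge into
#' one anomaly; missing weeks and cohort-year boundaries with date gaps
#' larger than the weekly grid break runs.
#'
#' @param series a weekly [daily_series()] of CPUE (see [weekly_series()]).
#' @param clim a week-keyed [build_climatology()] table.
#' @param min_duration_weeks minimum run length in weeks. Default 1.
#' @return `data.frame` of class `biotic_anomalies` with columns `group`,
#'   `sign`, `start_week`, `end_week`, `duration_weeks`, `magnitude`
#'   (signed sum of weekly CPUE exceedances beyond the crossed envelope).
#' @export
detect_biotic_anomalies <- function(series, clim, min_duration_weeks = 1L) {
  stopifnot(inherits(series, "daily_series"), identical(series$freq, "weekly"))
  u <- clim_units(clim, series)
  v <- series$values
  exceed <- weekly_exceedance(series, clim)
  state <- sign(exceed)
  state[is.na(v)] <- 9L
  # breaks between non-adjacent weeks (grid gap > 9 days covers the 8-9 day
  # final week of a cohort year)
  gap_break <- c(FALSE, diff(as.numeric(series$dates)) > 9)

  rows <- list()
  i <- 1L; n <- length(v)
  while (i <= n) {
    s <- state[i]
    if (is.na(s) || s == 0 || s == 9L) { i <- i + 1L; next }
    j <- i
    while (j < n && state[j + 1L] == s && !gap_break[j + 1L]) j <- j + 1L
    if (j - i + 1L >= min_duration_weeks) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = series$variable,
        sign = if (s > 0) "positive" else "negative",
        start_week = series$dates[i],
        end_week = series$dates[j],
        duration_weeks = j - i + 1L,
        magnitude = sum(exceed[i:j])
      )
    }
    i <- j + 1L
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(group = character(), sign = character(),
                      start_week = as.Date(character()),
                      end_week = as.Date(character()),
                      duration_weeks = integer(), magnitude = numeric())
  class(out) <- c("biotic_anomalies", "data.frame")
  out
}

# Per-week signed exceedance beyond the crossed envelope (0 inside, NA for
# missing weeks).
weekly_exceedance <- function(series, clim) {
  u <- clim_units(clim, series)
  v <- series$values
  ex <- numeric(length(v))
  ex[!is.na(v) & v > clim$upper[u]] <- (v - clim$upper[u])[!is.na(v) & v > clim$upper[u]]
  ex[!is.na(v) & v < clim$lower[u]] <- (v - clim$lower[u])[!is.na(v) & v < clim$lower[u]]
  ex[is.na(v)] <- NA_real_
  ex
}

#' Monthly mean and standard deviation of weekly CPUE
#'
#' Weeks are assigned to calendar months by their start date and treated as
#' replicates. Months inside the observed span with no usable weeks are
#' flagged missing; by default a month with a single week reports a missing
#' SD rather than zero.
#'
#' @param weekly a [compute_weekly_cpue()] table.
#' @param single_week_sd `"missing"` (default) or `"zero"`: SD convention
#'   for months with one week.
#' @return `data.frame` with columns `month` (`"YYYY-MM"`), `group`,
#'   `n_weeks`, `mean`, `sd`, `missing`.
#' @export
monthly_summary <- function(weekly, single_week_sd = c("missing", "zero")) {
  single_week_sd <- match.arg(single_week_sd)
  stopifnot(inherits(weekly, "weekly_cpue"))
  months <- format(weekly$week_start, "%Y-%m")
  span <- range(weekly$week_start)
  all_months <- format(seq(as.Date(paste0(format(span[1], "%Y-%m"), "-01")),
                           span[2], by = "month"), "%Y-%m")
  groups <- unique(weekly$group)
  grid <- expand.grid(month = all_months, group = groups,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    vals <- weekly$cpue[months == grid$month[i] & weekly$group == grid$group[i]]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    data.frame(
      month = grid$month[i], group = grid$group[i], n_weeks = n,
      mean = if (n > 0) mean(vals) else NA_real_,
      sd = if (n >= 2) stats::sd(vals)
           else if (n == 1 && single_week_sd == "zero") 0 else NA_real_,
      missing = n == 0L
    )
  })
  out <- do.call(rbind, res)
  out[order(out$month, out$group), ]
}
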