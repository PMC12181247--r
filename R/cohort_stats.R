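#' Cumulative anomaly sums per cohort year
#'
#' Aggregates detected anomalies into cohort years (01 August through 31
#' July, see [assign_cohort_year()]): the positive sum collects all
#' positive day-degrees (or weekly CPUE exceedances), the negative sum all
#' negative ones, and the net sum is their total. Events straddling the 31
#' July boundary are split day by day, so the split sums always conserve
#' the unsplit total.
#'
#' @param x an `anomaly_events` table (abiotic path) or a weekly
#'   [daily_series()] of CPUE (biotic path).
#' @param ... passed to methods.
#' @return `data.frame` of class `cohort_summary` with columns
#'   `cohort_year`, `variable`, `positive_sum`, `negative_sum`, `net_sum`,
#'   `n_anomaly_units` (days for abiotic, weeks for biotic).
#' @export
cohort_cumulative <- function(x, ...) UseMethod("cohort_cumulative")

#' @describeIn cohort_cumulative per-day day-degrees of detected events,
#'   computed against `baseline` (default the crossed envelope threshold,
#'   i.e. the net anomalous value; `"mean"` gives the climatological-mean
#'   intensity convention).
#' @param series,clim the series and climatology the anomalies were
#'   detected in.
#' @param baseline `"threshold"` or `"mean"`.
#' @param cohorts integer cohort-year labels to report; defaults to every
#'   cohort year touched by the series (zero rows for anomaly-free years).
#' @export
cohort_cumulative.anomaly_events <- function(x, series, clim,
                                             baseline = c("threshold", "mean"),
                                             cohorts = NULL, ...) {
  baseline <- match.arg(baseline)
  u <- clim_units(clim, series)
  ch <- assign_cohort_year(series$dates)
  if (is.null(cohorts)) cohorts <- seq(min(ch), max(ch))
  pos <- neg <- stats::setNames(numeric(length(cohorts)), cohorts)
  ndays <- stats::setNames(integer(length(cohorts)), cohorts)
  for (i in seq_len(nrow(x))) {
    idx <- match(seq(x$start[i], x$end[i], by = "day"), series$dates)
    base <- switch(baseline,
                   mean = clim$mean[u[idx]],
                   threshold = if (x$sign[i] == "positive") clim$upper[u[idx]]
                               else clim$lower[u[idx]])
    contrib <- series$values[idx] - base
    if (baseline == "threshold") {
      # inside-envelope gap days contribute zero net anomalous value
      if (x$sign[i] == "positive") contrib[contrib < 0] <- 0
      else contrib[contrib > 0] <- 0
    }
    key <- as.character(ch[idx])
    for (k in unique(key)) {
      if (!k %in% names(pos)) stop("anomaly outside configured cohort range")
      s <- sum(contrib[key == k])
      if (x$sign[i] == "positive") pos[k] <- pos[k] + s else neg[k] <- neg[k] + s
      ndays[k] <- ndays[k] + sum(key == k)
    }
  }
  out <- data.frame(cohort_year = as.integer(cohorts),
                    variable = attr(x, "variable") %||% series$variable,
                    positive_sum = as.numeric(pos), negative_sum = as.numeric(neg),
                    net_sum = as.numeric(pos + neg),
                    n_anomaly_units = as.integer(ndays))
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @describeIn cohort_cumulative weekly CPUE exceedances beyond the
#'   envelope summed per cohort year (week-level threshold filter; with a
#'   one-week minimum duration this equals summing merged anomalies).
#' @export
cohort_cumulative.daily_series <- function(x, clim, cohorts = NULL, ...) {
  stopifnot(identical(x$freq, "weekly"))
  ex <- weekly_exceedance(x, clim)
  ch <- assign_cohort_year(x$dates)
  if (is.null(cohorts)) cohorts <- seq(min(ch), max(ch))
  pos <- neg <- stats::setNames(numeric(length(cohorts)), cohorts)
  nw <- stats::setNames(integer(length(cohorts)), cohorts)
  ok <- !is.na(ex) & ex != 0
  for (i in which(ok)) {
    k <- as.character(ch[i])
    if (!k %in% names(pos)) stop("anomaly outside configured cohort range")
    if (ex[i] > 0) pos[k] <- pos[k] + ex[i] else neg[k] <- neg[k] + ex[i]
    nw[k] <- nw[k] + 1L
  }
  out <- data.frame(cohort_year = as.integer(cohorts), variable = x$variable,
                    positive_sum = as.numeric(pos), negative_sum = as.numeric(neg),
                    net_sum = as.numeric(pos + neg),
                    n_anomaly_units = as.integer(nw))
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Rank cohort years by a summary key
#'
#' Ascending ranks with average ranks for ties, so the most anomalous cold
#' spell year takes the lowest rank and the most anomalous heat wave year
#' the highest.
#'
#' @param summaries a `cohort_summary` table or a plain numeric vector.
#' @param key column to rank on when `summaries` is a table. Default
#'   `"net_sum"`.
#' @return numeric rank vector.
#' @export
rank_cohorts <- function(summaries, key = "net_sum") {
  x <- if (is.data.frame(summaries)) summaries[[key]] else summaries
  rank(x, ties.method = "average")
}

#' Ordinary least squares on rank-transformed anomaly sums
#'
#' Fits `y_ranks ~ x_ranks` by OLS. Rank transformation tames the skewed,
#' zero-bounded distribution of cumulative anomaly sums at the cost of the
#' metric information, making the usual normal-theory F and t tests
#' defensible at small n. For untied ranks the slope equals the Spearman
#' correlation of the underlying keys. A perfect fit (zero residual
#' variance) reports `F = Inf`, `t = +/-Inf`, `p = 0` by convention.
#'
#' @param x_ranks,y_ranks equal-length rank vectors, `n >= 3` (average
#'   ranks for ties allowed).
#' @return object of class `rank_regression`: `slope`, `intercept`,
#'   `t_value`, `F` (df 1 and `n - 2`), `r2`, `adj_r2`, `p_value`, `n`.
#' @export
rank_regression <- function(x_ranks, y_ranks) {
  n <- length(x_ranks)
  if (length(y_ranks) != n) stop("rank vectors differ in length")
  if (n < 3L) stop("need at least 3 paired ranks")
  if (stats::var(x_ranks) == 0) stop("zero variance in x ranks")
  fit <- stats::lm(y_ranks ~ x_ranks)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((y_ranks - mean(y_ranks))^2)
  rss <- stats::deviance(fit)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  if (rss <= 1e-10 * max(tss, 1)) {
    tval <- sign(slope) * Inf; Fval <- Inf; p <- 0; r2 <- 1; adj_r2 <- 1
  } else {
    sm <- summary(fit)
    tval <- sm$coefficients["x_ranks", "t value"]
    Fval <- tval^2
    p <- stats::pf(Fval, 1, n - 2, lower.tail = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, t_value = tval,
                 F = Fval, df1 = 1L, df2 = n - 2L, r2 = r2, adj_r2 = adj_r2,
                 p_value = p, n = n),
            class = "rank_regression")
}

#' @export
print.rank_regression <- function(x, digits = 3, ...) {
  cat("Rank-on-rank least-squares regression\n")
  cat(sprintf("  n = %d, slope = %s, t = %s, F(1,%d) = %s\n",
              x$n, format(x$slope, digits = digits),
              format(x$t_value, digits = digits), x$df2,
              format(x$F, digits = digits)))
  cat(sprintf("  r2 = %s, adj r2 = %s, p = %s\n",
              format(x$r2, digits = digits), format(x$adj_r2, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' @export
summary.rank_regression <- function(object, ...) object

#' @export
coef.rank_regression <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Mann-Kendall trend test
#'
#' Computes the signed pair-concordance sum `S = sum_{i<j} sign(x_j - x_i)`
#' and Kendall's tau with tie correction. For `n <= 10` without ties the
#' two-sided p-value comes from the exact null distribution of `S`
#' (inversion-count enumeration); otherwise from the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x ordered numeric sequence (one value per time step); missing
#'   values are dropped.
#' @return object of class `trend_test`: `tau`, `s_statistic`, `p_value`,
#'   `n`, `method`.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 non-missing values")
  S <- 0L
  for (i in seq_len(n - 1L))
    S <- S + sum(sign(x[(i + 1L):n] - x[i]))
  ties <- table(x)
  ties <- ties[ties > 1L]
  D <- n * (n - 1) / 2
  Tx <- sum(ties * (ties - 1) / 2)
  tau <- S / sqrt((D - Tx) * D)
  if (n <= 10L && length(ties) == 0L) {
    p <- mk_exact_p(S, n)
    method <- "exact"
  } else {
    varS <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    z <- if (S == 0L) 0 else (S - sign(S)) / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(tau = tau, s_statistic = as.integer(S),
                 p_value = min(p, 1), n = n, method = method),
            class = "trend_test")
}

# Exact two-sided p for S under the no-trend null (no ties): the null
# distribution of the inversion count follows the generating function
# prod_{k=1..n} (1 + z + ... + z^(k-1)).
mk_exact_p <- function(S, n) {
  counts <- 1
  for (k in 2:n) {
    new <- numeric(length(counts) + k - 1L)
    for (j in 0:(k - 1L))
      new[seq_along(counts) + j] <- new[seq_along(counts) + j] + counts
    counts <- new
  }
  probs <- counts / sum(counts)
  D <- n * (n - 1) / 2
  s_vals <- D - 2 * (seq_along(probs) - 1L)  # S for each inversion count
  if (S == 0L) return(1)
  min(1, 2 * sum(probs[s_vals >= abs(S)]))
}

#' @export
print.trend_test <- function(x, digits = 3, ...) {
  cat("Mann-Kendall trend test (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, S = %d, tau = %s, p = %s\n", x$n, x$s_statistic,
              format(x$tau, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}

#' Trend tests on per-cohort anomaly frequency and intensity
#'
#' Builds the standard per-cohort-year series -- event counts (frequency,
#' both signs pooled) and cumulative absolute day-degrees per sign
#' (intensity) -- and runs [mann_kendall()] on each.
#'
#' @param events an `anomaly_events` table.
#' @param series,clim the series and climatology of the detection run.
#' @param cohorts cohort-year labels; defaults to the series span.
#' @param baseline intensity baseline, `"threshold"` or `"mean"`.
#' @return `data.frame` with one row per test: `variable`, `series`,
#'   `tau`, `s_statistic`, `p_value`, `n`.
#' @export
anomaly_trend_tests <- function(events, series, clim, cohorts = NULL,
                                baseline = c("threshold", "mean")) {
  baseline <- match.arg(baseline)
  ch <- assign_cohort_year(series$dates)
  if (is.null(cohorts)) cohorts <- seq(min(ch), max(ch))
  ev_cohort <- assign_cohort_year(events$start)
  freq <- sapply(cohorts, function(y) sum(ev_cohort == y))
  summ <- cohort_cumulative(events, series, clim, baseline = baseline,
                            cohorts = cohorts)
  specs <- list(
    frequency = freq,
    intensity_positive = abs(summ$positive_sum),
    intensity_negative = abs(summ$negative_sum)
  )
  rows <- lapply(names(specs), function(nm) {
    tt <- mann_kendall(specs[[nm]])
    data.frame(variable = attr(events, "variable") %||% series$variable,
               series = nm, tau = tt$tau, s_statistic = tt$s_statistic,
               p_value = tt$p_value, n = tt$n)
  })
  do.call(rbind, rows)
}

#' Rank-regression coupling of abiotic and biotic cohort anomalies
#'
#' Ranks the per-cohort net anomaly sums of an abiotic variable and of a
#' biotic CPUE series over the same cohort years and regresses the biotic
#' ranks on the abiotic ranks. When groups are excluded, the community
#' total is rebuilt from the remaining groups' weekly CPUE *before*
#' climatology construction and anomaly detection -- anomalies are
#' nonlinear in the envelope, so excluded groups cannot simply be
#' subtracted afterwards.
#'
#' @param abiotic_summaries a `cohort_summary` table for the abiotic
#'   variable (e.g. temperature day-degrees).
#' @param weekly a [compute_weekly_cpue()] table.
#' @param group biotic group to couple, or `"TOTAL"` for the community.
#' @param exclude_groups groups removed before rebuilding the total.
#' @param clim_args extra arguments for the weekly [build_climatology()].
#' @param key ranking key column. Default `"net_sum"`.
#' @return a [rank_regression()] object with added fields `group` and
#'   `excluded`.
#' @export
coupling_analysis <- function(abiotic_summaries, weekly, group = "TOTAL",
                              exclude_groups = character(),
                              clim_args = list(), key = "net_sum") {
  stopifnot(inherits(abiotic_summaries, "cohort_summary"))
  ser <- weekly_series(weekly, group = group, exclude_groups = exclude_groups)
  clim <- do.call(build_climatology, c(list(ser), clim_args))
  cohorts <- abiotic_summaries$cohort_year
  bio <- cohort_cumulative(ser, clim, cohorts = cohorts)
  if (!identical(bio$cohort_year, cohorts)) stop("cohort sets differ")
  res <- rank_regression(rank_cohorts(abiotic_summaries, key),
                         rank_cohorts(bio, key))
  res$group <- group
  res$excluded <- exclude_groups
  res$biotic_summaries <- bio
  res
}

#' Coupling statistics for the community and every biotic group
#'
#' Convenience wrapper running [coupling_analysis()] for the integrated
#' community (`TOTAL`), each group separately and, optionally, the
#' community with named groups excluded.
#'
#' @inheritParams coupling_analysis
#' @param exclusion_variants named list of group-label vectors; each entry
#'   adds a rebuilt-total variant (e.g.
#'   `list(no_jellyfish = "jellyfish")`).
#' @return `data.frame` with one row per configuration: `configuration`,
#'   `n`, `slope`, `t_value`, `F`, `r2`, `adj_r2`, `p_value`.
#' @export
coupling_table <- function(abiotic_summaries, weekly,
                           exclusion_variants = list(),
                           clim_args = list(), key = "net_sum") {
  groups <- setdiff(unique(weekly$group), "TOTAL")
  configs <- c(list(TOTAL = list(group = "TOTAL", exclude = character())),
               stats::setNames(lapply(groups, function(g)
                 list(group = g, exclude = character())), groups),
               lapply(exclusion_variants, function(ex)
                 list(group = "TOTAL", exclude = ex)))
  rows <- lapply(names(configs), function(nm) {
    cf <- configs[[nm]]
    r <- coupling_analysis(abiotic_summaries, weekly, group = cf$group,
                           exclude_groups = cf$exclude,
                           clim_args = clim_args, key = key)
    data.frame(configuration = nm, n = r$n, slope = r$slope,
               t_value = r$t_value, F = r$F, r2 = r$r2, adj_r2 = r$adj_r2,
               p_value = r$p_value)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
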