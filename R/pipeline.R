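#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with either a `scenario:` block of
#' [scenario_config()] arguments or an `inputs:` block of file paths and
#' column schemas, plus optional `climatology:`, `events:`, `biotic:` and
#' `stats:` parameter blocks and a `seed:`.
#'
#' @param path path to the config file.
#' @return the configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the full anomaly-coupling pipeline
#'
#' Executes the stages in order -- data generation or ingest, daily
#' aggregation, climatology construction, event detection for temperature
#' and salinity, weekly CPUE standardization, biotic anomaly detection,
#' cohort-year aggregation, Mann-Kendall trend tests and rank-regression
#' coupling -- and writes every intermediate table as CSV plus a JSON run
#' manifest recording parameters, seed and input digests. Reruns with the
#' same config and inputs reproduce byte-identical tables.
#'
#' @param config a configuration list (see [read_run_config()]) or a path
#'   to a config file.
#' @param outdir output directory, created if needed.
#' @param seed overrides the config seed when not `NULL`.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  p_clim <- config$climatology %||% list()
  p_ev <- config$events %||% list()
  p_bio <- config$biotic %||% list()
  p_stats <- config$stats %||% list()
  digests <- list()

  if (!is.null(config$scenario)) {
    scen <- stage("generate", {
      args <- config$scenario
      args$seed <- seed
      if (!is.null(args$injected_events))
        args$injected_events <- lapply(args$injected_events, as.list)
      if (!is.null(args$biota)) args$biota <- as.data.frame(args$biota)
      do.call(scenario_config, args)
    })
    gen <- stage("generate", generate_scenario(scen))
    temp <- gen$temperature; sal <- gen$salinity; records <- gen$records
    write_daily_series(temp, file.path(outdir, "daily_temperature.csv"))
    write_daily_series(sal, file.path(outdir, "daily_salinity.csv"))
    utils::write.csv(as.data.frame(records)[
      c("week_start", "image_pairs",
        setdiff(names(records), c("week_start", "image_pairs")))],
      file.path(outdir, "survey_records.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(gen$truth$events, file.path(outdir, "truth_events.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(gen$truth$cohort_net_day_degrees,
                     file.path(outdir, "truth_cohort_day_degrees.csv"),
                     row.names = FALSE, quote = FALSE)
  } else if (!is.null(config$inputs)) {
    ing <- stage("ingest", {
      read_daily <- function(entry, variable) {
        if (!is.null(entry$daily) && isTRUE(entry$daily))
          read_daily_series(entry$path, variable = variable)
        else {
          smp <- read_series(entry$path,
                             schema = entry$schema %||%
                               list(timestamp = "timestamp", value = "value"))
          aggregate_daily(smp,
                          min_coverage = entry$min_coverage %||% 0.5,
                          expected_per_day = entry$expected_per_day,
                          variable = variable)
        }
      }
      temp <- read_daily(config$inputs$temperature, "temperature")
      sal <- read_daily(config$inputs$salinity, "salinity")
      records <- utils::read.csv(config$inputs$survey$path,
                                 stringsAsFactors = FALSE)
      records$week_start <- as.Date(records$week_start)
      list(temp = temp, sal = sal, records = records)
    })
    temp <- ing$temp; sal <- ing$sal; records <- ing$records
    digests <- lapply(list(temperature = config$inputs$temperature$path,
                           salinity = config$inputs$salinity$path,
                           survey = config$inputs$survey$path),
                      function(p) unname(tools::md5sum(p)))
  } else stop("config must provide either a scenario or inputs")

  clim_args <- list(window_halfwidth = p_clim$window_halfwidth,
                    smooth_span = p_clim$smooth_span,
                    percentile_pair = unlist(p_clim$percentile_pair %||%
                                               c(0.1, 0.9)))
  clim_args <- clim_args[!vapply(clim_args, is.null, logical(1))]

  clims <- stage("climatology", list(
    temperature = do.call(build_climatology, c(list(temp), clim_args)),
    salinity = do.call(build_climatology, c(list(sal), clim_args))
  ))
  for (vn in names(clims))
    utils::write.csv(as.data.frame(clims[[vn]]),
                     file.path(outdir, paste0("climatology_", vn, ".csv")),
                     row.names = FALSE, quote = FALSE)

  min_dur <- p_ev$min_duration %||% 5L
  max_gap <- p_ev$max_gap %||% 0L
  events <- stage("events", rbind(
    detect_events(temp, clims$temperature, min_dur, max_gap),
    detect_events(sal, clims$salinity, min_dur, max_gap)
  ))
  utils::write.csv(events, file.path(outdir, "events.csv"),
                   row.names = FALSE, quote = FALSE)

  weekly <- stage("biotic", compute_weekly_cpue(
    records, effort_floor = p_bio$effort_floor %||% 48))
  utils::write.csv(weekly, file.path(outdir, "weekly_cpue.csv"),
                   row.names = FALSE, quote = FALSE)

  wclim_args <- list(window_halfwidth = p_bio$window_halfwidth,
                     smooth_span = p_bio$smooth_span)
  wclim_args <- wclim_args[!vapply(wclim_args, is.null, logical(1))]
  bio_anoms <- stage("biotic", {
    total <- weekly_series(weekly, "TOTAL")
    wclim <- do.call(build_climatology, c(list(total), wclim_args))
    list(series = total, clim = wclim,
         anomalies = detect_biotic_anomalies(
           total, wclim,
           min_duration_weeks = p_bio$min_duration_weeks %||% 1L))
  })
  utils::write.csv(bio_anoms$anomalies,
                   file.path(outdir, "biotic_anomalies.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(monthly_summary(weekly),
                   file.path(outdir, "monthly_summary.csv"),
                   row.names = FALSE, quote = FALSE)

  cohort <- stage("cohort", {
    tev <- events[events$variable == "temperature", ]
    sev <- events[events$variable == "salinity", ]
    class(tev) <- class(sev) <- c("anomaly_events", "data.frame")
    attr(tev, "variable") <- "temperature"; attr(sev, "variable") <- "salinity"
    ch_all <- assign_cohort_year(temp$dates)
    cohorts <- seq(min(ch_all), max(ch_all))
    base <- p_ev$baseline %||% "threshold"
    rbind(
      cohort_cumulative(tev, temp, clims$temperature, baseline = base,
                        cohorts = cohorts),
      cohort_cumulative(sev, sal, clims$salinity, baseline = base,
                        cohorts = cohorts),
      cohort_cumulative(bio_anoms$series, bio_anoms$clim, cohorts = cohorts)
    )
  })
  utils::write.csv(cohort, file.path(outdir, "cohort_summaries.csv"),
                   row.names = FALSE, quote = FALSE)

  stats_out <- stage("stats", {
    tev <- events[events$variable == "temperature", ]
    sev <- events[events$variable == "salinity", ]
    class(tev) <- class(sev) <- c("anomaly_events", "data.frame")
    attr(tev, "variable") <- "temperature"; attr(sev, "variable") <- "salinity"
    trends <- rbind(
      anomaly_trend_tests(tev, temp, clims$temperature),
      anomaly_trend_tests(sev, sal, clims$salinity)
    )
    tsumm <- cohort[cohort$variable == "temperature", ]
    class(tsumm) <- c("cohort_summary", "data.frame")
    variants <- p_stats$exclusion_variants %||% list(no_jellyfish = "jellyfish")
    reg <- coupling_table(tsumm, weekly,
                          exclusion_variants = variants,
                          clim_args = wclim_args,
                          key = p_stats$ranking_key %||% "net_sum")
    list(trends = trends, regressions = reg)
  })
  utils::write.csv(stats_out$trends, file.path(outdir, "trend_tests.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(stats_out$regressions, file.path(outdir, "regressions.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "fjordwave",
    version = as.character(utils::packageVersion("fjordwave")),
    seed = seed,
    parameters = list(climatology = clim_args, events = list(
      min_duration = min_dur, max_gap = max_gap,
      baseline = p_ev$baseline %||% "threshold"),
      biotic = c(wclim_args,
                 list(effort_floor = p_bio$effort_floor %||% 48,
                      min_duration_weeks = p_bio$min_duration_weeks %||% 1L)),
      stats = list(ranking_key = p_stats$ranking_key %||% "net_sum",
                   multiple_testing = "none")),
    input_digests = digests,
    outputs = list.files(outdir, pattern = "\\.csv$")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(temperature = temp, salinity = sal, climatologies = clims,
                 events = events, weekly = weekly,
                 biotic_anomalies = bio_anoms$anomalies,
                 cohort_summaries = cohort, trends = stats_out$trends,
                 regressions = stats_out$regressions, manifest = manifest))
}
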