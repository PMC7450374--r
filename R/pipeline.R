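# Pipeline entry points.
#
# The package is used from R; run_pipeline() exposes the workflow stages as
# named subcommands over a validated config list, writing CSV/JSON outputs
# and a run manifest so any run is reproducible from its config.

write_json_out <- function(x, path, force) {
  if (!force && file.exists(path))
    stop(path, " exists; use force = TRUE to overwrite")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Commands: `simulate` (write a seeded synthetic patient-year as event-log
#' CSV plus ground-truth CSV), `preprocess` (event log to smoothed daily
#' series CSV), `weekly` (per-episode deviation table), `density`
#' (baseline-vs-full ratio density comparison), `detect` (per-day status
#' CSV and metrics JSON), `report` (deviation table of the five bundled
#' reference infection cases).  Every command validates its config before
#' touching any file, never overwrites outputs unless `force = TRUE`, and
#' writes a `run_manifest.json` recording command, config and package
#' version.  Identical config and inputs give identical outputs.
#'
#' @param command One of `"simulate"`, `"preprocess"`, `"weekly"`,
#'   `"density"`, `"detect"`, `"report"`.
#' @param config Named list.  Common fields: `input` (event-log directory),
#'   `output` (output directory), `force` (overwrite flag).  `simulate`
#'   accepts the [sim_config()] fields plus `onset_day`/`duration_days` for
#'   a single episode; `detect` accepts `thresholds` and `basis`; `density`
#'   accepts `mode` and `tail_quantile`; `weekly` accepts `anchor_offset`.
#' @return Invisible list of the objects the command produced.
#' @export
run_pipeline <- function(command = c("simulate", "preprocess", "weekly",
                                     "density", "detect", "report"),
                         config = list()) {
  command <- match.arg(command)
  stopifnot(is.list(config))
  out_dir <- config$output
  if (is.null(out_dir)) stop("config$output (output directory) is required")
  force <- isTRUE(config$force)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  load_input <- function() {
    if (is.null(config$input)) stop("config$input (event-log directory) is required")
    read_event_log(config$input)
  }

  result <- switch(command,
    simulate = {
      eps <- list()
      if (!is.null(config$onset_day))
        eps <- list(episode_config(config$onset_day,
                                   config$duration_days %||% 10))
      keep <- intersect(names(config), names(formals(sim_config)))
      cfg <- do.call(sim_config, c(config[keep], list(episodes = eps)))
      sim <- generate_patient_year(cfg)
      write_event_log(sim$log, out_dir, force = force)
      tf <- file.path(out_dir, "ground_truth.csv")
      if (!force && file.exists(tf))
        stop(tf, " exists; use force = TRUE to overwrite")
      utils::write.csv(sim$truth, tf, row.names = FALSE)
      sim
    },
    preprocess = {
      log <- load_input()
      daily <- moving_average(resample(log, "day"),
                              config$window_hours %||% 48)
      write_series(daily, file.path(out_dir, "smoothed_daily.csv"),
                   force = force)
      list(smoothed = daily)
    },
    weekly = {
      log <- load_input()
      if (!nrow(log$infections)) stop("event log reports no infections")
      reports <- do.call(rbind, lapply(seq_len(nrow(log$infections)),
        function(i) case_report(log, i, config$anchor_offset %||% 0L)))
      tab <- format_deviation_report(reports)
      f <- file.path(out_dir, "weekly_deviation.csv")
      if (!force && file.exists(f))
        stop(f, " exists; use force = TRUE to overwrite")
      utils::write.csv(tab, f, row.names = FALSE)
      list(reports = reports)
    },
    density = {
      log <- load_input()
      smoothed <- moving_average(resample(log, "day"))
      cmp <- compare_densities(smoothed, log$infections,
                               mode = config$mode %||% "ratio_1d",
                               tail_quantile = config$tail_quantile %||% 0.99)
      write_density(cmp$full, file.path(out_dir, "density_full.csv"),
                    force = force)
      if (cmp$mode == "ratio_1d")
        write_density(cmp$baseline,
                      file.path(out_dir, "density_baseline.csv"),
                      force = force)
      write_json_out(list(excess_tail_mass = cmp$excess_tail_mass,
                          baseline_support_hi = cmp$baseline_support_hi,
                          max_observed = cmp$max_observed,
                          n_baseline = cmp$n_baseline, n_full = cmp$n_full),
                     file.path(out_dir, "density_comparison.json"), force)
      list(comparison = cmp)
    },
    detect = {
      log <- load_input()
      thr <- config$thresholds %||% DEFAULT_THRESHOLDS
      det <- detect_microevents(log, thresholds = thr,
                                basis = config$basis %||% "ratio_tail")
      f <- file.path(out_dir, "status.csv")
      if (!force && file.exists(f))
        stop(f, " exists; use force = TRUE to overwrite")
      utils::write.csv(as.data.frame(det$status), f, row.names = FALSE)
      det
    },
    report = {
      tab <- format_deviation_report(reference_case_reports())
      f <- file.path(out_dir, "reference_cases.csv")
      if (!force && file.exists(f))
        stop(f, " exists; use force = TRUE to overwrite")
      utils::write.csv(tab, f, row.names = FALSE)
      agg <- reference_case_aggregates()
      write_json_out(list(
        aggregates = agg$deviations, ratio_mean_pct = agg$ratio_mean_pct),
        file.path(out_dir, "reference_aggregates.json"), force)
      list(reports = tab, aggregates = agg)
    })

  manifest <- list(command = command,
                   config = config[setdiff(names(config), "force")],
                   package_version = as.character(
                     utils::packageVersion("glucodetect")),
                   timestamp = format_ts(Sys.time()))
  mf <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
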