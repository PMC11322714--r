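run_config_defaults <- function() {
  list(mode = "simulate",
       study_start = "2020-01-01", study_end = "2020-08-27",
       cutoff_date = "2020-03-23", cutoff_day = NULL,
       bandwidth = "auto", sensitivity_delta = 20L, sensitivity_step = 5L,
       age_boundaries = c(25L, 30L), variance = "HC0",
       horizon_days = 999, seed = 20200101L,
       events_file = NULL, registry_file = NULL, sim = list())
}

#' Validate and normalize a pipeline run configuration
#'
#' Fills defaults, performs the calendar arithmetic (2020 is a leap year, so
#' the default period 2020-01-01 to 2020-08-27 spans 240 days and the cutoff
#' date 2020-03-23 is day 82), and rejects contradictory settings: unknown
#' keys, a cutoff outside the period, a non-positive bandwidth, or a
#' sensitivity range whose lower end falls below 5 days.
#'
#' @param config named list of settings; see `Details` for keys.
#' @return normalized `run_config` list with `study_days` and `cutoff_day`
#'   resolved.
#' @details Keys: `mode` ("simulate" or "real-data"), `study_start`,
#'   `study_end`, `cutoff_date` or `cutoff_day`, `bandwidth` ("auto" or
#'   days), `sensitivity_delta`, `sensitivity_step`, `age_boundaries`,
#'   `variance` ("HC0", "HC1", "cluster"), `horizon_days`, `seed`,
#'   `events_file`, `registry_file`, `sim` (overrides for [sim_config()]).
#' @export
validate_run_config <- function(config = list()) {
  defaults <- run_config_defaults()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  if (!cfg$mode %in% c("simulate", "real-data")) {
    stop("mode must be 'simulate' or 'real-data'")
  }
  cfg$study_days <- study_length(cfg$study_start, cfg$study_end)
  if (is.null(cfg$cutoff_day)) {
    cfg$cutoff_day <- study_day(cfg$cutoff_date, cfg$study_start)
  }
  if (cfg$cutoff_day < 0 || cfg$cutoff_day >= cfg$study_days) {
    stop("cutoff (day ", cfg$cutoff_day, ") outside the study period of ",
         cfg$study_days, " days")
  }
  if (!identical(cfg$bandwidth, "auto")) {
    if (!is.numeric(cfg$bandwidth) || cfg$bandwidth < 2) {
      stop("bandwidth must be 'auto' or a number of days >= 2")
    }
    if (cfg$bandwidth - cfg$sensitivity_delta < 5) {
      stop("sensitivity delta ", cfg$sensitivity_delta,
           " leaves bandwidths below 5 days (bandwidth ", cfg$bandwidth, ")")
    }
  }
  if (!cfg$variance %in% c("HC0", "HC1", "cluster")) {
    stop("variance must be HC0, HC1 or cluster")
  }
  if (cfg$mode == "real-data" &&
      (is.null(cfg$events_file) || is.null(cfg$registry_file))) {
    stop("real-data mode requires events_file and registry_file")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    stop("seed must be a single integer")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline run configuration from YAML
#' @param path YAML file path with [validate_run_config()] keys.
#' @return a normalized `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

pipeline_log <- function(lines, path) {
  cat(lines, file = path, sep = "\n", append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate-or-load, panel construction, bandwidth selection,
#' the segmented modified Poisson fits, age-stratified recovery times, and
#' the bandwidth sensitivity scan, writing all tables plus a log (seed,
#' versions, per-stage event counts) to `out_dir`. Identical configuration
#' and seed give identical outputs.
#'
#' @param config a `run_config` (or raw list, normalized internally).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the panels, fits, report, recovery and
#'   sensitivity tables, and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  pipeline_log(c(paste("rdtime", as.character(utils::packageVersion("rdtime"))),
                 paste("R", getRversion()),
                 paste("seed", config$seed),
                 paste("mode", config$mode),
                 paste("study_days", config$study_days,
                       "cutoff_day", config$cutoff_day)), logf)
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, TRUE)],
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pipeline_log(paste("FAILED at stage", name, ":", conditionMessage(e)),
                   logf)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  panels <- stage("input", {
    if (config$mode == "simulate") {
      sim_args <- utils::modifyList(
        list(n_users = 3416L, study_days = config$study_days,
             cutoff_day = config$cutoff_day, seed = config$seed),
        config$sim)
      sim <- do.call(sim_config, sim_args)
      simulate_panel(sim)$panels
    } else {
      events <- load_events(config$events_file, config$study_start,
                            config$study_end)
      registry <- load_registry(config$registry_file, config$age_boundaries,
                                config$study_start)
      val <- validate_constraints(events)
      pipeline_log(paste("constraint violations:", nrow(val$violations)), logf)
      stats::setNames(lapply(OUTCOME_TYPES, function(oc) {
        binarize(val$events, registry, config$study_days, oc,
                 config$cutoff_day, config$study_start)
      }), OUTCOME_TYPES)
    }
  })
  panels <- Filter(function(p) sum(p$y) > 0L, panels)
  if (length(panels) == 0L) stop("no events in any outcome panel")

  fits <- list(); sens <- list(); bw <- integer(0)
  for (oc in names(panels)) {
    panel <- panels[[oc]]
    s <- summarize_panel(panel)
    write_panel_summary(s, file.path(out_dir,
                                     paste0("panel_summary_", oc, ".json")))
    pipeline_log(sprintf("%s: %d person-days, %d events (%d pre / %d post)",
                         oc, s$person_days, s$events_total, s$events_pre,
                         s$events_post), logf)
    h <- stage(paste0("bandwidth_", oc), {
      if (identical(config$bandwidth, "auto")) {
        ik_bandwidth(daily_rates(panel), config$cutoff_day)$h_opt
      } else as.integer(config$bandwidth)
    })
    bw[oc] <- h
    pipeline_log(paste0(oc, ": bandwidth ", h, " days"), logf)
    fits[[oc]] <- stage(paste0("rdd_", oc),
                        fit_rdd(panel, h, cutoff_day = config$cutoff_day,
                                variance = config$variance))
    sens[[oc]] <- stage(paste0("sensitivity_", oc), {
      sc <- sensitivity_scan(panel, h, delta = config$sensitivity_delta,
                             step = config$sensitivity_step,
                             cutoff_day = config$cutoff_day,
                             variance = config$variance)
      utils::write.csv(sc, file.path(out_dir,
                                     paste0("sensitivity_", oc, ".csv")),
                       row.names = FALSE)
      sc
    })
  }

  report <- report_table(fits)
  write_report(report, file.path(out_dir, "report"))

  recovery <- stage("recovery", {
    rec <- recovery_by_age(panels, bandwidths = bw,
                           cutoff_day = config$cutoff_day,
                           horizon_days = config$horizon_days,
                           variance = config$variance)
    export_recovery(rec, file.path(out_dir, "recovery.csv"))
    rec
  })

  pipeline_log("done", logf)
  invisible(list(panels = panels, fits = fits, report = report,
                 recovery = recovery, sensitivity = sens,
                 bandwidths = bw, out_dir = out_dir))
}
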