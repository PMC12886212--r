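#' Resolve a dataset argument
#'
#' `"study"` (or the path-less alias `"packaged"`) resolves to the packaged
#' trial dataset; anything else is read as an interchange CSV.
#'
#' @param dataset `"study"` or a CSV path.
#' @return `fbi_trial` data frame.
#' @keywords internal
resolve_dataset <- function(dataset) {
  if (identical(dataset, "study") || identical(dataset, "packaged")) {
    fbi_trial()
  } else {
    read_trial(dataset)
  }
}

run_header <- function(out_dir, command, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- list(command = command,
              package_version = as.character(utils::packageVersion("fbidose")),
              config = config)
  jsonlite::write_json(hdr, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  message(sprintf("[fbidose %s] %s: %s", hdr$package_version, command,
                  jsonlite::toJSON(config, auto_unbox = TRUE,
                                   null = "null")))
  invisible(hdr)
}

#' Replay a trial and write its artifacts
#'
#' Writes the decision trace (JSON), the per-duration outcome summary (CSV),
#' and a short human-readable report.
#'
#' @param dataset `"study"` or a CSV path.
#' @param out_dir output directory (created if needed).
#' @return invisible list of written paths.
#' @export
run_replay <- function(dataset = "study", out_dir = "fbidose_replay") {
  run_header(out_dir, "replay", list(dataset = dataset))
  dat <- resolve_dataset(dataset)
  trace <- replay_trial(dat)
  paths <- list(trace = file.path(out_dir, "trace.json"),
                summary = file.path(out_dir, "cohort_summary.csv"),
                report = file.path(out_dir, "report.txt"))
  trace_to_json(trace, paths$trace)
  write.csv(cohort_summary(dat), paths$summary, row.names = FALSE)
  lines <- c(
    sprintf("Dose ladder: %s",
            paste(trace$steps$target_dose_min, collapse = " -> ")),
    sprintf("Maximal tolerated dose: %s min",
            format(trace$maximal_tolerated_dose)),
    sprintf("Recommended dose: %s min", format(trace$recommended_dose)),
    sprintf("Terminated: %s (rule %s)", trace$terminated,
            trace$termination_rule),
    if (length(trace$warnings)) paste("Warning:", trace$warnings))
  writeLines(lines, paths$report)
  invisible(paths)
}

#' Run the analysis stack and write its artifacts
#'
#' Writes the dose-response model summary table (CSV) and a JSON report with
#' the paired threshold tests, the ownership correlation, the per-duration
#' summaries, and the baseline-adjusted ANCOVA.
#'
#' @inheritParams run_replay
#' @param whole_minutes passed to [regression_durations()].
#' @return invisible list of written paths.
#' @export
run_analyze <- function(dataset = "study", out_dir = "fbidose_analysis",
                        whole_minutes = TRUE) {
  run_header(out_dir, "analyze",
             list(dataset = dataset, whole_minutes = whole_minutes))
  dat <- resolve_dataset(dataset)
  if (nrow(dat) < 5) {
    stop("too few participants for the analysis stack (need >= 5)",
         call. = FALSE)
  }
  paths <- list(models = file.path(out_dir, "model_summaries.csv"),
                results = file.path(out_dir, "results.json"))
  write.csv(model_summary_table(dat, whole_minutes = whole_minutes),
            paths$models, row.names = FALSE)
  x <- regression_durations(dat, whole_minutes = whole_minutes)
  ch <- change_scores(dat, "t1", "t2", "nrs")
  lin <- fit_polynomial(x, ch, 1)
  quad <- fit_polynomial(x, ch, 2)
  pt_l <- paired_t(dat$ppt_left_t1, dat$ppt_left_t2)
  pt_r <- paired_t(dat$ppt_right_t1, dat$ppt_right_t2)
  an <- ancova(dat$nrs_t2, dat$nrs_t1, factor(dat$target_dose_min))
  res <- list(
    nrs_lrt = lrt(lin, quad),
    paired_ppt_left = unclass(pt_l),
    paired_ppt_right = unclass(pt_r),
    ownership_correlation = pearson_test(dat$ownership, ch),
    ancova = list(f_factor = an$f_factor, df_factor = an$df_factor,
                  df_resid = an$df_resid, p_factor = an$p_factor,
                  eta2_factor = an$eta2_factor,
                  f_covariate = an$f_covariate,
                  p_covariate = an$p_covariate,
                  eta2_covariate = an$eta2_covariate,
                  emms = as.list(an$emms), pairwise = an$pairwise),
    cohort_summary = cohort_summary(dat))
  res$paired_ppt_left$lm <- NULL
  jsonlite::write_json(res, paths$results, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(paths)
}

#' Simulate adaptive trials and write their artifacts
#'
#' With one replication, writes the simulated dataset (interchange CSV) and
#' its decision trace; with several, additionally writes the
#' operating-characteristics summary as JSON and CSV.
#'
#' @param model [population_model()], or a YAML/JSON file of its fields.
#' @param reps number of replications.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisible list of written paths.
#' @export
run_simulate <- function(model = population_model(), reps = 1L, seed = 1L,
                         out_dir = "fbidose_sim") {
  if (is.character(model)) model <- read_model_file(model)
  stopifnot(inherits(model, "population_model"))
  run_header(out_dir, "simulate",
             list(reps = reps, seed = seed,
                  model = unclass(model)))
  cfg <- sim_config(seed = seed, n_replications = reps)
  paths <- list()
  sim <- simulate_trial(model, cfg)
  paths$dataset <- file.path(out_dir, "simulated_trial.csv")
  paths$trace <- file.path(out_dir, "simulated_trace.json")
  write_trial(sim$dataset, paths$dataset)
  trace_to_json(sim$trace, paths$trace)
  if (reps > 1) {
    oc <- operating_characteristics(model, cfg)
    paths$oc_json <- file.path(out_dir, "operating_characteristics.json")
    paths$oc_csv <- file.path(out_dir, "recommended_doses.csv")
    jsonlite::write_json(unclass(oc), paths$oc_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
    write.csv(oc$recommended, paths$oc_csv, row.names = FALSE)
  }
  invisible(paths)
}

read_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML model files",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(population_model, vals)
}

#' Demonstrate the cardio-visual synchrony pipeline
#'
#' Generates a synthetic ECG, runs the full filtering/detection/scheduling
#' pipeline, and writes the trace, detected peaks, frame schedule, and
#' latency report.
#'
#' @param duration seconds of synthetic ECG (default 60).
#' @param hr_bpm heart rate (default 60, must lie in (30, 200)).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param ... further arguments to [sync_pipeline()].
#' @return invisible list of written paths.
#' @export
run_syncdemo <- function(duration = 60, hr_bpm = 60, seed = 1L,
                         out_dir = "fbidose_sync", ...) {
  run_header(out_dir, "syncdemo",
             list(duration = duration, hr_bpm = hr_bpm, seed = seed))
  trace <- synth_ecg(duration, hr_bpm = hr_bpm, hr_jitter_sd = 0.03,
                     noise_sd = 0.02, seed = seed)
  pipe <- sync_pipeline(trace, ...)
  paths <- list(trace = file.path(out_dir, "ecg.csv"),
                peaks = file.path(out_dir, "r_peaks.csv"),
                schedule = file.path(out_dir, "frames.csv"),
                report = file.path(out_dir, "latency.json"))
  write_ecg(trace, paths$trace,
            sidecar = file.path(out_dir, "ecg_true_peaks.csv"))
  write.csv(pipe$events, paths$peaks, row.names = FALSE)
  write.csv(pipe$schedule[, c("time", "opacity", "particle_intensity")],
            paths$schedule, row.names = FALSE)
  jsonlite::write_json(unclass(pipe$report), paths$report,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}
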