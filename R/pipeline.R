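#' Default pipeline configuration
#'
#' Layered defaults for the simulate/analyze/report pipeline. The base
#' layer carries the acquisition and analysis parameters the pipeline
#' targets: 7.8 Hz, 60-s spontaneous and 120-s evoked sessions, epoch
#' threshold 3, 10-s quietest window, 1,000 scrambles, 10,000 rank-bootstrap
#' resamples, alpha 0.05. User values (a named list or a YAML file) override
#' defaults key by key.
#'
#' @param config named list or path to a YAML file; `NULL` keeps defaults.
#' @return named list of class `run_config`.
#' @export
load_config <- function(config = NULL) {
  defaults <- list(
    seed = 1L, n_neurons = 30L,
    frame_rate_hz = 7.8, spont_duration_s = 60, evoked_duration_s = 120,
    window_s = 10, threshold = 3, decay_tau_s = 1.5,
    n_scrambles = 1000L, n_resamples = 10000L, alpha = 0.05,
    baseline_method = "running_percentile",
    log_level = "INFO")
  user <- if (is.null(config)) list()
          else if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config
          else stop("config must be a list or a YAML path", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, user)
  .assert_scalar_num(out$alpha, "alpha", min = 0, max = 1)
  .assert_scalar_num(out$threshold, "threshold")
  .assert_scalar_num(out$n_scrambles, "n_scrambles", min = 1)
  structure(out, class = c("run_config", "list"))
}

.log <- function(cfg, level, fmt, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "INFO"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Simulate a full synthetic dataset to disk
#'
#' Generates the longitudinal dataset ([generate_developmental_dataset()])
#' and writes per-stage spontaneous and evoked trace CSVs (with JSON
#' sidecars) plus a `manifest.json` recording every parameter, per-session
#' seed and output file checksum. Re-running with the same config produces
#' byte-identical trace CSVs.
#'
#' @param config see [load_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
run_simulate <- function(config = NULL, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  t0 <- Sys.time()
  ds <- generate_developmental_dataset(
    seed = cfg$seed, n_neurons = cfg$n_neurons,
    spont_duration_s = cfg$spont_duration_s,
    evoked_duration_s = cfg$evoked_duration_s,
    frame_rate_hz = cfg$frame_rate_hz)
  files <- character(0)
  for (stage in names(ds$stages)) {
    st <- ds$stages[[stage]]
    for (kind in c("spontaneous", "evoked")) {
      f <- file.path(out_dir, sprintf("%s_%s.csv", stage, kind))
      extra <- list(stage = stage, kind = kind, seed = st$config$seed)
      if (kind == "evoked")
        extra$protocol <- list(onsets_s = st$protocol$onsets_s,
                               epoch_duration_s = st$protocol$epoch_duration_s,
                               isi_s = st$protocol$isi_s,
                               n_stimuli = st$protocol$n_stimuli)
      write_traces(st[[kind]], f, extra = extra)
      files <- c(files, f, paste0(f, ".json"))
    }
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(cfg),
    stages = names(ds$stages),
    roi_ids = ds$roi_ids,
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(cfg, "INFO", "simulate: wrote %d files to %s in %.1f s",
       length(files) + 1, out_dir,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}

.read_manifest <- function(dataset_dir) {
  mf <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(mf))
    stop("missing manifest: ", mf, call. = FALSE)
  jsonlite::read_json(mf, simplifyVector = TRUE)
}

# rebuild a session_set from a simulated dataset directory
.load_session_set <- function(dataset_dir) {
  manifest <- .read_manifest(dataset_dir)
  stages <- list()
  for (stage in manifest$stages) {
    sp_f <- file.path(dataset_dir, sprintf("%s_spontaneous.csv", stage))
    ev_f <- file.path(dataset_dir, sprintf("%s_evoked.csv", stage))
    sp <- tryCatch(read_traces(sp_f), error = function(e)
      stop("failed reading ", sp_f, ": ", conditionMessage(e), call. = FALSE))
    ev <- tryCatch(read_traces(ev_f), error = function(e)
      stop("failed reading ", ev_f, ": ", conditionMessage(e), call. = FALSE))
    pr <- attr(ev, "meta")$protocol
    stages[[stage]] <- list(
      spontaneous = sp, evoked = ev,
      protocol = stimulus_protocol(onsets_s = pr$onsets_s,
                                   epoch_duration_s = pr$epoch_duration_s))
  }
  rois <- manifest$roi_ids
  structure(list(stages = stages, roi_ids = rois,
                 master_seed = as.integer(manifest$config$seed)),
            class = "session_set")
}

#' Analyze a simulated or user-supplied dataset directory
#'
#' Reads the dataset manifest and trace CSVs, runs the full analysis
#' ([analyze_development()]) and writes: per-stage epoch tables and
#' responsiveness CSVs, correlation matrices, the stage summary table, and
#' a `stats.json` with the Friedman omnibus and parameter provenance.
#'
#' @param config see [load_config()]; analysis parameters are taken from
#'   here (the dataset's own generation parameters live in its manifest).
#' @param dataset_dir directory produced by [run_simulate()].
#' @param results_dir output directory.
#' @return invisibly, the `ca_development` fit.
#' @export
run_analyze <- function(config = NULL, dataset_dir, results_dir) {
  cfg <- load_config(config)
  ds <- .load_session_set(dataset_dir)
  dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  fit <- analyze_development(ds, window_s = cfg$window_s,
                             threshold = cfg$threshold,
                             decay_tau_s = cfg$decay_tau_s,
                             n_scrambles = cfg$n_scrambles,
                             alpha = cfg$alpha, seed = cfg$seed)
  prov <- list(window_s = cfg$window_s, threshold = cfg$threshold,
               decay_tau_s = cfg$decay_tau_s, n_scrambles = cfg$n_scrambles,
               alpha = cfg$alpha, seed = cfg$seed,
               dataset = normalizePath(dataset_dir))
  for (stage in names(ds$stages)) {
    z <- modified_zscore(ds$stages[[stage]]$spontaneous,
                         window_s = cfg$window_s, threshold = cfg$threshold)
    write_epochs(detect_epochs(z),
                 file.path(results_dir, sprintf("%s_epochs.csv", stage)),
                 extra = prov)
    resp <- fit$responsiveness[[stage]]
    utils::write.csv(as.data.frame(resp),
                     file.path(results_dir,
                               sprintf("%s_responsiveness.csv", stage)),
                     row.names = FALSE)
    utils::write.csv(fit$correlations[[stage]]$matrix,
                     file.path(results_dir,
                               sprintf("%s_correlation_matrix.csv", stage)))
  }
  utils::write.csv(as.data.frame(fit$summary),
                   file.path(results_dir, "stage_summary.csv"),
                   row.names = FALSE)
  stats_out <- list(
    provenance = prov,
    active_rois = fit$active_rois,
    friedman = if (!is.null(fit$friedman))
      list(statistic = fit$friedman$statistic,
           p_value = fit$friedman$p_value,
           method = fit$friedman$method,
           posthoc = fit$friedman$posthoc))
  jsonlite::write_json(stats_out, file.path(results_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(cfg, "INFO", "analyze: wrote results to %s in %.1f s", results_dir,
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(fit)
}

#' Render a human-readable report from a results directory
#'
#' Writes `report.txt` (the stage summary table plus the omnibus test) and,
#' when `figures = TRUE`, PNG figures of the synchrony and responsiveness
#' trajectories. Never mutates the results directory contents it reads;
#' re-running overwrites the report identically.
#'
#' @param results_dir directory produced by [run_analyze()].
#' @param report_dir where to write the report (defaults to `results_dir`).
#' @param figures write PNG figures.
#' @return invisibly, the path to `report.txt`.
#' @export
run_report <- function(results_dir, report_dir = results_dir,
                       figures = TRUE) {
  summ_f <- file.path(results_dir, "stage_summary.csv")
  stats_f <- file.path(results_dir, "stats.json")
  if (!file.exists(summ_f) || !file.exists(stats_f))
    stop("incomplete results directory (need stage_summary.csv and stats.json): ",
         results_dir, call. = FALSE)
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- utils::read.csv(summ_f, stringsAsFactors = FALSE)
  st <- jsonlite::read_json(stats_f, simplifyVector = TRUE)
  rpt <- file.path(report_dir, "report.txt")
  con <- file(rpt, "w")
  writeLines("Developmental desynchronization report", con)
  writeLines(strrep("=", 40), con)
  writeLines(utils::capture.output(print(summ, digits = 3, row.names = FALSE)), con)
  if (!is.null(st$friedman))
    writeLines(sprintf("\nFriedman omnibus: chi2 = %.3f, p = %.3g (%s)",
                       st$friedman$statistic, st$friedman$p_value,
                       st$friedman$method), con)
  writeLines(sprintf("\nActive ROIs at all stages: %d",
                     length(st$active_rois)), con)
  close(con)
  if (figures) {
    grDevices::png(file.path(report_dir, "synchrony.png"), 600, 450)
    graphics::plot(seq_len(nrow(summ)), summ$mean_pairwise, type = "b",
                   pch = 19, xaxt = "n", xlab = "stage",
                   ylab = "mean pairwise r", main = "Network synchrony")
    graphics::axis(1, at = seq_len(nrow(summ)), labels = summ$stage)
    grDevices::dev.off()
    grDevices::png(file.path(report_dir, "responsiveness.png"), 600, 450)
    graphics::plot(seq_len(nrow(summ)), summ$responsive_fraction, type = "b",
                   pch = 19, xaxt = "n", ylim = c(0, 1), xlab = "stage",
                   ylab = "responsive fraction",
                   main = "Whisker responsiveness")
    graphics::axis(1, at = seq_len(nrow(summ)), labels = summ$stage)
    grDevices::dev.off()
  }
  invisible(rpt)
}
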