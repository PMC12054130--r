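#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or
#'   `"from_csv_dir"` (read trace CSVs plus sidecars from a directory).
#' @param out_dir output directory (created if absent).
#' @param seed master seed; in simulate mode it seeds the cohort, and it
#'   is recorded in the manifest either way.
#' @param sim_config a [cohort_config()] for simulate mode; its `seed`
#'   is overridden by `seed`.
#' @param input_dir directory of trace CSVs for `from_csv_dir` mode.
#' @param fit_window_s length-2 vector: pre/post fit window (s).
#' @param saccade_threshold_deg_s rebound-saccade velocity threshold
#'   (deg/s).
#' @param figures render a per-subject trajectory figure.
#' @param spearman_method passed to [summarize_cohort()].
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "from_csv_dir"),
                       out_dir,
                       seed = 1L,
                       sim_config = cohort_config(),
                       input_dir = NULL,
                       fit_window_s = c(10, 10),
                       saccade_threshold_deg_s = 30,
                       figures = FALSE,
                       spearman_method = "auto") {
  mode <- match.arg(mode)
  if (mode == "from_csv_dir") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("`input_dir` must be an existing directory in from_csv_dir mode",
           call. = FALSE)
    }
  }
  stopifnot(length(fit_window_s) == 2L, all(fit_window_s > 0))
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 sim_config = sim_config, input_dir = input_dir,
                 fit_window_s = fit_window_s,
                 saccade_threshold_deg_s = saccade_threshold_deg_s,
                 figures = figures, spearman_method = spearman_method),
            class = "run_config")
}

load_cohort_dir <- function(input_dir) {
  files <- sort(list.files(input_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no trace CSVs in ", input_dir, call. = FALSE)
  lapply(files, function(f) {
    tr <- read_trace_csv(f)
    sid <- if (is.null(tr$subject_id)) {
      sub("\\.csv$", "", basename(f))
    } else {
      tr$subject_id
    }
    diag <- if (is.null(tr$diagnosis)) "exophoria" else tr$diagnosis
    apct <- if (is.null(tr$apct_pd)) NA_real_ else tr$apct_pd
    if (!is.finite(apct)) apct <- 0
    cohort_record(subject_id = sid, diagnosis = diag, apct_pd = apct,
                  trace = tr)
  })
}

#' Run the cover-test analysis pipeline end to end
#'
#' Simulation or ingestion, per-trace logistic fitting and metric
#' extraction, cohort summary statistics, optional figures, and a run
#' manifest, all written under `config$out_dir`:
#' \describe{
#'   \item{`traces/`}{per-subject trace CSVs + sidecars (simulate mode)}
#'   \item{`metrics.csv`}{one row of deviation metrics per subject}
#'   \item{`summary.json`}{cohort summary (means, category counts,
#'     correlations, APCT comparison)}
#'   \item{`figures/`}{per-subject trajectory figures (optional)}
#'   \item{`manifest.json`}{configuration, seed, package version and any
#'     excluded subjects with reasons}
#' }
#' Subjects whose fit fails or does not converge are excluded from the
#' summary and listed in the manifest. Identical configuration and seed
#' produce byte-identical tables.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `records`, `metrics` (data.frame),
#'   `summary`, `excluded` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "simulate") {
    sim <- config$sim_config
    sim$seed <- config$seed
    records <- simulate_cohort(sim)
    tr_dir <- file.path(out, "traces")
    dir.create(tr_dir, showWarnings = FALSE)
    for (r in records) {
      write_trace_csv(r$trace, file.path(tr_dir, paste0(r$subject_id, ".csv")))
    }
  } else {
    records <- load_cohort_dir(config$input_dir)
  }

  excluded <- list()
  fitted <- list()
  for (r in records) {
    res <- tryCatch({
      fit <- suppressWarnings(
        fit_logistic(r$trace, config$fit_window_s[1], config$fit_window_s[2]))
      if (!isTRUE(fit$converged)) stop("logistic fit did not converge")
      m <- suppressWarnings(trace_metrics(
        r$trace, fit = fit,
        saccade_threshold_deg_s = config$saccade_threshold_deg_s))
      r$metrics <- m
      r
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "cohort_record")) {
      fitted[[length(fitted) + 1L]] <- res
    } else {
      excluded[[r$subject_id]] <- res
    }
  }
  if (length(fitted) < 2L) {
    stop("fewer than 2 subjects survived fitting; nothing to summarize",
         call. = FALSE)
  }

  tab <- metrics_table(fitted)
  metrics_path <- file.path(out, "metrics.csv")
  write_metrics_csv(tab, metrics_path)

  summ <- summarize_cohort(fitted, spearman_method = config$spearman_method)
  summ_json <- list(
    n = summ$n, n_exophoria = summ$n_exophoria,
    n_by_diagnosis = as.list(summ$n_by_diagnosis),
    mean_sd_angle_deg = as.list(summ$mean_sd_angle_deg),
    mean_sd_angle_pd = as.list(summ$mean_sd_angle_pd),
    mean_sd_peak_speed = as.list(summ$mean_sd_peak_speed),
    mean_sd_stab_time_s = as.list(summ$mean_sd_stab_time_s),
    mean_sd_overshoot_deg = as.list(summ$mean_sd_overshoot_deg),
    category_counts = as.list(summ$category_counts),
    corr_angle_speed = unclass(summ$corr_angle_speed),
    corr_angle_stabtime = unclass(summ$corr_angle_stabtime),
    corr_depth_speed = unclass(summ$corr_depth_speed),
    apct_vs_device = summ$apct_vs_device)
  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(summ_json, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (isTRUE(config$figures)) {
    fig_dir <- file.path(out, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (r in fitted) {
      suppressWarnings(render_trace_figure(
        r$trace, attr(r$metrics, "fit"), r$metrics,
        file.path(fig_dir, paste0(r$subject_id, ".png"))))
    }
  }

  manifest <- list(
    mode = config$mode,
    seed = config$seed,
    fit_window_s = config$fit_window_s,
    saccade_threshold_deg_s = config$saccade_threshold_deg_s,
    spearman_method = config$spearman_method,
    sim_config = if (config$mode == "simulate") {
      unclass(config$sim_config)
    } else {
      NULL
    },
    input_dir = config$input_dir,
    n_subjects_in = length(records),
    n_subjects_analyzed = length(fitted),
    excluded = excluded,
    package_version = as.character(utils::packageVersion("covertrace")))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(records = fitted, metrics = tab, summary = summ,
                 excluded = excluded,
                 paths = list(metrics = metrics_path, summary = summary_path,
                              manifest = manifest_path)))
}
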