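#' Two-sided paired t-test
#'
#' Thin validated wrapper around [stats::t.test()] for paired samples,
#' used to compare alternate prism cover test values with device-measured
#' deviations on a common prism-diopter scale.
#'
#' @param x,y paired numeric vectors, n >= 2.
#' @return list with `t`, `p_value`, `df` and `mean_diff` (mean of
#'   `x - y`).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate paired test: differences have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))

#' Cohort-level summary of cover-test metrics
#'
#' Computes, over the exophoria subgroup: mean and SD of the deviation
#' angle (degrees and per-subject prism-diopter conversions), peak
#' deviation speed, stabilization time and overshoot depth; counts per
#' overshoot category; and the three Spearman rank correlations of
#' interest (angle vs speed, angle vs stabilization time, overshoot
#' depth vs speed). Over all records, the alternate prism cover test
#' value is compared against the device-measured deviation (converted
#' per subject to PD) with a paired t-test. Tropic cases contribute only
#' to the paired comparison and are otherwise reported individually.
#'
#' @param records list of [cohort_record()] objects with `metrics`
#'   computed (see [trace_metrics()]).
#' @param spearman_method passed to [spearman_rank()]; default `"auto"`.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, spearman_method = "auto") {
  stopifnot(is.list(records), length(records) >= 2L)
  no_metrics <- vapply(records, function(r) is.null(r$metrics), logical(1))
  if (any(no_metrics)) {
    ids <- vapply(records[no_metrics], function(r) r$subject_id, character(1))
    stop("records without computed metrics: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  tab <- metrics_table(records)
  exo <- tab[tab$diagnosis == "exophoria", , drop = FALSE]
  if (nrow(exo) < 3L) {
    stop("need at least 3 exophoria records for correlations", call. = FALSE)
  }
  cat_counts <- c(gt1 = sum(exo$overshoot_category == "gt1"),
                  mid = sum(exo$overshoot_category == "mid"),
                  lt0p5 = sum(exo$overshoot_category == "lt0p5"))
  device_pd <- tab$angle_pd
  out <- list(
    n = nrow(tab),
    n_by_diagnosis = table(tab$diagnosis),
    n_exophoria = nrow(exo),
    mean_sd_angle_deg = mean_sd(exo$angle_deg),
    mean_sd_angle_pd = mean_sd(exo$angle_pd),
    mean_sd_peak_speed = mean_sd(exo$peak_speed_deg_s),
    mean_sd_stab_time_s = mean_sd(exo$stabilization_time_s),
    mean_sd_overshoot_deg = mean_sd(exo$overshoot_depth_deg),
    category_counts = cat_counts,
    corr_angle_speed = spearman_rank(exo$angle_deg, exo$peak_speed_deg_s,
                                     method = spearman_method),
    corr_angle_stabtime = spearman_rank(exo$angle_deg, exo$stabilization_time_s,
                                        method = spearman_method),
    corr_depth_speed = spearman_rank(exo$overshoot_depth_deg, exo$peak_speed_deg_s,
                                     method = spearman_method),
    apct_vs_device = paired_t_test(tab$apct_pd, device_pd))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  f <- function(ms) sprintf("%.2f +/- %.2f", ms["mean"], ms["sd"])
  cat(sprintf("Cohort summary (%d subjects, %d exophoria)\n", x$n, x$n_exophoria))
  cat("  deviation angle:    ", f(x$mean_sd_angle_deg), "deg (",
      f(x$mean_sd_angle_pd), "PD )\n")
  cat("  peak speed:         ", f(x$mean_sd_peak_speed), "deg/s\n")
  cat("  stabilization time: ", f(x$mean_sd_stab_time_s), "s\n")
  cat("  overshoot depth:    ", f(x$mean_sd_overshoot_deg), "deg\n")
  cat(sprintf("  overshoot categories: >1: %d, 0.5-1: %d, <0.5: %d\n",
              x$category_counts["gt1"], x$category_counts["mid"],
              x$category_counts["lt0p5"]))
  pr <- function(lbl, cr) {
    cat(sprintf("  %s: rs = %.3f, p = %.4f (%s)\n", lbl, cr$rs, cr$p_value,
                cr$method))
  }
  pr("angle vs speed     ", x$corr_angle_speed)
  pr("angle vs stab. time", x$corr_angle_stabtime)
  pr("depth vs speed     ", x$corr_depth_speed)
  cat(sprintf("  APCT vs device: mean diff = %.2f PD, t = %.3f, p = %.4g\n",
              x$apct_vs_device$mean_diff, x$apct_vs_device$t,
              x$apct_vs_device$p_value))
  invisible(x)
}

#' Flatten cohort records into a per-subject metrics table
#'
#' @param records list of [cohort_record()] objects with metrics.
#' @return data.frame, one row per subject, columns for all metrics plus
#'   `subject_id`, `diagnosis`, `apct_pd`.
#' @export
metrics_table <- function(records) {
  rows <- lapply(records, function(r) {
    m <- r$metrics
    if (is.null(m)) stop("record ", r$subject_id, " has no metrics", call. = FALSE)
    data.frame(subject_id = r$subject_id,
               diagnosis = r$diagnosis,
               apct_pd = r$apct_pd,
               angle_deg = m$angle_deg,
               angle_pd = m$angle_pd,
               peak_speed_deg_s = m$peak_speed_deg_s,
               raw_peak_speed_deg_s = m$raw_peak_speed_deg_s,
               stabilization_time_s = m$stabilization_time_s,
               overshoot_depth_deg = m$overshoot_depth_deg,
               overshoot_category = m$overshoot_category,
               max_deviation_deg = m$max_deviation_deg,
               rebound_saccade = m$rebound_saccade,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
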