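#' Construct a gaze trace
#'
#' A `gaze_trace` holds one trial's horizontal gaze time series for both
#' eyes on a uniform sampling grid around an occlusion event. By
#' convention occlusion onset is at time 0 s, with pre-onset samples
#' negative, and gaze angles are in degrees in a shared rightward-positive
#' coordinate frame.
#'
#' @param time_s numeric vector of sample times (s), uniformly spaced;
#'   must straddle 0 (onset strictly inside the record).
#' @param fixating_deg horizontal gaze of the eye that is never occluded
#'   (deg).
#' @param covered_deg horizontal gaze of the occluded eye (deg).
#' @param covered_eye_side `"left"` or `"right"`.
#' @param fs_hz sampling rate (Hz).
#' @param missing logical vector flagging dropout samples (e.g. blinks);
#'   gaze values at flagged samples are ignored downstream.
#' @param subject_id optional subject identifier.
#' @param diagnosis optional diagnosis label (`"exophoria"`,
#'   `"intermittent_exotropia"` or `"exotropia"`).
#' @param apct_pd optional alternate prism cover test value (prism
#'   diopters, exo negative).
#' @param ground_truth optional named list of generating parameters and
#'   analytic metrics (attached by the simulator).
#'
#' @return An object of class `gaze_trace`: a list with elements
#'   `time_s`, `fixating_deg`, `covered_deg`, `missing`,
#'   `covered_eye_side`, `fs_hz` and the optional metadata.
#' @export
gaze_trace <- function(time_s, fixating_deg, covered_deg,
                       covered_eye_side = c("right", "left"),
                       fs_hz = 30,
                       missing = rep(FALSE, length(time_s)),
                       subject_id = NULL, diagnosis = NULL,
                       apct_pd = NULL, ground_truth = NULL) {
  covered_eye_side <- match.arg(covered_eye_side)
  n <- length(time_s)
  if (length(fixating_deg) != n || length(covered_deg) != n ||
      length(missing) != n) {
    stop("time, gaze and missing vectors must have equal length",
         call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    stop("`fs_hz` must be a single positive number", call. = FALSE)
  }
  if (n < 2L) stop("a gaze trace needs at least two samples", call. = FALSE)
  dt <- diff(time_s)
  bad <- which(abs(dt - 1 / fs_hz) > 1e-6)
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-uniform sampling: gap between samples %d and %d is %.6f s (expected %.6f s)",
      bad[1L], bad[1L] + 1L, dt[bad[1L]], 1 / fs_hz), call. = FALSE)
  }
  if (!(min(time_s) < 0 && max(time_s) > 0)) {
    stop("occlusion onset (t = 0) must lie strictly inside the record",
         call. = FALSE)
  }
  missing <- as.logical(missing)
  ok <- !missing
  if (any(!is.finite(fixating_deg[ok])) || any(!is.finite(covered_deg[ok]))) {
    stop("non-missing gaze samples must be finite", call. = FALSE)
  }
  if (!is.null(diagnosis)) {
    diagnosis <- match.arg(diagnosis,
                           c("exophoria", "intermittent_exotropia", "exotropia"))
  }
  if (!is.null(apct_pd) && !is.finite(apct_pd)) {
    stop("`apct_pd` must be finite", call. = FALSE)
  }
  structure(
    list(time_s = as.numeric(time_s),
         fixating_deg = as.numeric(fixating_deg),
         covered_deg = as.numeric(covered_deg),
         missing = missing,
         covered_eye_side = covered_eye_side,
         fs_hz = fs_hz,
         subject_id = subject_id,
         diagnosis = diagnosis,
         apct_pd = apct_pd,
         ground_truth = ground_truth),
    class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "<gaze_trace> %d samples @ %g Hz, t in [%.2f, %.2f] s, covered eye: %s\n",
    length(x$time_s), x$fs_hz, min(x$time_s), max(x$time_s),
    x$covered_eye_side))
  if (!is.null(x$subject_id)) {
    cat(sprintf("  subject: %s (%s)\n", x$subject_id,
                if (is.null(x$diagnosis)) "?" else x$diagnosis))
  }
  if (any(x$missing)) {
    cat(sprintf("  %d missing (blink) samples\n", sum(x$missing)))
  }
  invisible(x)
}

#' Signed deviation signal of a trace
#'
#' The ocular deviation is the difference between the occluded eye's gaze
#' and the fixating eye's gaze, signed so that exodeviation (temporal
#' drift of the covered eye) is negative and esodeviation positive,
#' whichever eye is covered. In the shared rightward-positive frame a
#' temporally deviated covered right eye sits at a more positive angle
#' than the fixating eye, so the raw difference is negated when the
#' covered eye is the right one.
#'
#' @param trace a [gaze_trace()].
#' @return numeric vector of per-sample deviations (deg), `NA` at
#'   missing samples.
#' @export
deviation_signal <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  dev <- trace$covered_deg - trace$fixating_deg
  if (trace$covered_eye_side == "right") dev <- -dev
  dev[trace$missing] <- NA_real_
  dev
}
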