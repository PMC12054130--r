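#' Fit the four-parameter logistic deviation model to one trace
#'
#' Least-squares fit of `L0 + a / (1 + exp(-k (t - t0)))` to the signed
#' deviation signal over a window around occlusion onset, by
#' Levenberg-Marquardt with box bounds on the rate. Starting values come
#' from the data: `L0` from the pre-onset median, `a` from the post-onset
#' tail median, `t0` from the half-crossing time, and `k` from the
#' 25-75% crossing interval (the logistic rises 25% to 75% over
#' `2 ln 3 / k`). Missing samples are excluded from the loss; no
#' interpolation is performed.
#'
#' Because the symmetric logistic is monotone, an overshoot transient in
#' the data would otherwise drag the fitted asymptote beyond the true
#' final position and mask the very excursion being measured. The fit is
#' therefore made overshoot-aware: after an initial pass, post-onset
#' samples lying beyond the fitted far asymptote (in the deviation
#' direction, by more than twice the residual RMS) are excluded and the
#' model refitted, iterating until no new samples are flagged. On
#' monotone traces no sample is ever flagged and the result is the plain
#' least-squares fit.
#'
#' @param trace a [gaze_trace()].
#' @param window_pre_s,window_post_s fit window half-lengths (s),
#'   default 10 each.
#' @return object of class `logistic_fit`: a list with `baseline_deg`
#'   (`L0`), `deviation_a_deg` (`a`), `rate_k_per_s` (`k`),
#'   `midpoint_t0_s` (`t0`), `rmse_deg`, `converged`, `n_used` and
#'   `small_deviation` (`TRUE` when the fitted deviation — the smaller of
#'   `|a|` and the realized in-window change of the fitted curve — is
#'   under twice the residual noise).
#' @export
fit_logistic <- function(trace, window_pre_s = 10, window_post_s = 10) {
  stopifnot(inherits(trace, "gaze_trace"))
  dev <- deviation_signal(trace)
  t <- trace$time_s
  keep <- t >= -window_pre_s & t <= window_post_s & !is.na(dev)
  t <- t[keep]; y <- dev[keep]
  n_pre <- sum(t < 0); n_post <- sum(t > 0)
  if (n_pre < 8L || n_post < 8L) {
    stop(sprintf(
      "too few usable samples for fitting (%d pre-onset, %d post-onset; need >= 8 each)",
      n_pre, n_post), call. = FALSE)
  }

  # data-driven initialization
  L0_0 <- stats::median(y[t < 0])
  tail_y <- y[t > max(t) - 2]
  a_0 <- stats::median(tail_y) - L0_0
  if (abs(a_0) < 1e-8) a_0 <- if (a_0 < 0) -1e-3 else 1e-3
  frac <- (y - L0_0) / a_0
  cross <- function(level) {
    idx <- which(t > 0 & frac >= level)
    if (length(idx) == 0L) max(t) else t[idx[1L]]
  }
  t0_0 <- cross(0.5)
  dt75 <- cross(0.75) - cross(0.25)
  k_0 <- 2 * log(3) / max(dt75, 1 / trace$fs_hz)
  k_0 <- min(max(k_0, 0.05), 150)

  # Levenberg-Marquardt with analytic Jacobian; par = (L0, a, k, t0)
  do_fit <- function(t, y, start) {
    resid_fn <- function(par) {
      par[1] + par[2] * stats::plogis(par[3] * (t - par[4])) - y
    }
    jac_fn <- function(par) {
      p <- stats::plogis(par[3] * (t - par[4]))
      pq <- p * (1 - p)
      cbind(L0 = rep(1, length(t)), a = p,
            k = par[2] * pq * (t - par[4]),
            t0 = -par[2] * pq * par[3])
    }
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = unlist(start), fn = resid_fn, jac = jac_fn,
        # the midpoint must lie inside the record: an occlusion response
        # centered beyond the data is extrapolation, not measurement
        lower = c(-Inf, -Inf, 0.01, min(t)), upper = c(Inf, Inf, 200, max(t)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res$par))) return(NULL)
    res
  }
  start <- list(L0 = L0_0, a = a_0, k = k_0, t0 = t0_0)
  fit <- do_fit(t, y, start)

  # overshoot-aware refit: drop post-onset samples beyond the fitted far
  # asymptote, so a transient excursion cannot drag the asymptote with it
  if (!is.null(fit)) {
    drop <- rep(FALSE, length(t))
    for (it in seq_len(5L)) {
      cf <- fit$par
      s <- sign(cf[["a"]])
      if (s == 0) break
      rmse_it <- sqrt(mean(fit$fvec^2))
      far <- cf[["L0"]] + cf[["a"]]
      beyond <- t > 0 & s * (y - far) > 2 * rmse_it + 1e-9 & !drop
      if (!any(beyond)) break
      cand <- drop | beyond
      if (sum(!cand & t > 0) < 8L) break
      refit <- do_fit(t[!cand], y[!cand], as.list(cf))
      if (is.null(refit)) break
      drop <- cand
      fit <- refit
    }
    if (any(drop)) {
      t <- t[!drop]; y <- y[!drop]
    }
  }

  if (is.null(fit)) {
    res <- list(baseline_deg = L0_0, deviation_a_deg = a_0,
                rate_k_per_s = NA_real_, midpoint_t0_s = t0_0,
                rmse_deg = NA_real_, converged = FALSE,
                n_used = length(y), small_deviation = NA)
    class(res) <- "logistic_fit"
    return(res)
  }
  cf <- fit$par
  rmse <- sqrt(mean(fit$fvec^2))
  # converged: the optimizer reported a proper convergence criterion (not an
  # iteration limit or failure) and the rate is interior to its bounds
  ok_info <- fit$info %in% 1:4
  at_bound <- cf[["k"]] <= 0.01 + 1e-9 || cf[["k"]] >= 200 - 1e-6 ||
    cf[["t0"]] <= min(t) + 1e-9 || cf[["t0"]] >= max(t) - 1e-9
  # realized deviation change across the window; for a midpoint inside the
  # window this is essentially |a|, but it stays honest when the optimizer
  # extrapolates the asymptote far beyond the record
  lg <- function(tt) cf[["a"]] * stats::plogis(cf[["k"]] * (tt - cf[["t0"]]))
  realized <- abs(lg(max(t)) - lg(min(t)))
  small <- min(abs(cf[["a"]]), realized) < 2 * rmse
  if (small) {
    warning("small-deviation fit: |a| is below twice the residual noise",
            call. = FALSE)
  }
  res <- list(baseline_deg = unname(cf["L0"]),
              deviation_a_deg = unname(cf["a"]),
              rate_k_per_s = unname(cf["k"]),
              midpoint_t0_s = unname(cf["t0"]),
              rmse_deg = rmse,
              converged = ok_info && !at_bound,
              n_used = length(y),
              small_deviation = small)
  class(res) <- "logistic_fit"
  res
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> L0 = %.3f deg, a = %.3f deg, k = %.3f /s, t0 = %.3f s\n",
    x$baseline_deg, x$deviation_a_deg, x$rate_k_per_s, x$midpoint_t0_s))
  cat(sprintf("  rmse = %.4f deg, n = %d, converged: %s\n",
              x$rmse_deg, x$n_used, x$converged))
  invisible(x)
}

#' Evaluate a fitted logistic curve
#'
#' @param fit a [fit_logistic()] result.
#' @param t times (s).
#' @return fitted deviation values (deg).
#' @export
predict_logistic <- function(fit, t) {
  stopifnot(inherits(fit, "logistic_fit"))
  fit$baseline_deg + fit$deviation_a_deg *
    stats::plogis(fit$rate_k_per_s * (t - fit$midpoint_t0_s))
}

stop_if_not_converged <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    stop("metric unavailable: logistic fit did not converge", call. = FALSE)
  }
}

#' Peak deviation speed of a fitted logistic
#'
#' The logistic's maximum absolute slope, `|a| k / 4`, attained at the
#' midpoint `t0`.
#'
#' @param fit a converged [fit_logistic()] result.
#' @return peak speed (deg/s).
#' @export
peak_speed <- function(fit) {
  stop_if_not_converged(fit)
  abs(fit$deviation_a_deg) * fit$rate_k_per_s / 4
}

#' Stabilization time of a fitted logistic
#'
#' The earliest time after occlusion onset at which the fitted curve
#' reaches 90% of its asymptotic deviation from the baseline:
#' `t0 + ln(9) / k` in closed form. If the deviation has already passed
#' the 90% level at onset (midpoint far before onset), 0 is returned
#' with a warning.
#'
#' @param fit a converged [fit_logistic()] result.
#' @return time from occlusion onset (s).
#' @export
stabilization_time <- function(fit) {
  stop_if_not_converged(fit)
  t_star <- fit$midpoint_t0_s + log(9) / fit$rate_k_per_s
  if (t_star <= 0) {
    warning("deviation already at 90% of its asymptote at occlusion onset",
            call. = FALSE)
    return(0)
  }
  t_star
}

#' Overshoot depth and maximum deviation of a trace
#'
#' The most extreme post-onset value of the deviation signal (smoothed
#' with a 3-sample running median) in the direction of the fitted
#' deviation, and the depth by which it exceeds the fitted asymptote:
#' `depth = max(0, |max_deviation - L0| - |a|)`. A monotone approach
#' yields depth 0. Because the overshoot is a property of the raw
#' excursion (the symmetric logistic is monotone and cannot overshoot),
#' it is measured on the smoothed signal, not the fitted curve.
#'
#' @param trace a [gaze_trace()].
#' @param fit the converged [fit_logistic()] result for that trace.
#' @return list with `depth_deg` (>= 0) and `max_deviation_deg`.
#' @export
overshoot_depth <- function(trace, fit) {
  stop_if_not_converged(fit)
  dev <- deviation_signal(trace)
  post <- trace$time_s > 0 & !is.na(dev)
  y <- dev[post]
  if (length(y) < 3L) stop("too few post-onset samples", call. = FALSE)
  sm <- stats::runmed(y, 3)
  a <- fit$deviation_a_deg
  max_dev <- if (a < 0) min(sm) else max(sm)
  depth <- max(0, abs(max_dev - fit$baseline_deg) - abs(a))
  list(depth_deg = depth, max_deviation_deg = max_dev)
}

#' Classify an overshoot depth
#'
#' Categories: `"gt1"` for depths above 1 degree, `"mid"` for 0.5-1
#' degree inclusive, `"lt0p5"` below 0.5 degree.
#'
#' @param depth_deg overshoot depth (deg, >= 0).
#' @return category string.
#' @export
classify_overshoot <- function(depth_deg) {
  if (!is.finite(depth_deg) || depth_deg < 0) {
    stop("`depth_deg` must be a finite nonnegative number", call. = FALSE)
  }
  if (depth_deg > 1) "gt1" else if (depth_deg >= 0.5) "mid" else "lt0p5"
}

#' Detect a rebound-saccade in the refixating eye
#'
#' A rebound-saccade is a corrective saccade opposite to the initial
#' refixation saccade: the refixating eye overshoots the target, then
#' snaps back. Detection uses the central-difference velocity of the
#' uncovered (fixating-channel) eye after onset: `TRUE` when a
#' suprathreshold movement in one direction is followed, within
#' `window_s`, by a suprathreshold movement in the opposite direction.
#' Phoric drifts (a few deg/s) never cross a saccadic threshold.
#'
#' @param trace a [gaze_trace()].
#' @param threshold_deg_s saccade velocity threshold (deg/s), default 30.
#' @param window_s maximum interval between the two movements (s),
#'   default 1.
#' @return logical flag.
#' @export
detect_rebound_saccade <- function(trace, threshold_deg_s = 30, window_s = 1) {
  stopifnot(inherits(trace, "gaze_trace"))
  post <- trace$time_s > 0 & !trace$missing
  x <- trace$fixating_deg[post]
  t <- trace$time_s[post]
  n <- length(x)
  if (n < 3L) return(FALSE)
  v <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  tv <- t[2:(n - 1)]
  fast <- which(abs(v) > threshold_deg_s)
  if (length(fast) == 0L) return(FALSE)
  first <- fast[1L]
  sgn <- sign(v[first])
  opp <- fast[sign(v[fast]) == -sgn & (tv[fast] - tv[first]) <= window_s &
                tv[fast] > tv[first]]
  length(opp) > 0L
}

#' Maximum raw finite-difference deviation speed
#'
#' Auxiliary speed estimate taken directly from the (unsmoothed)
#' deviation signal after onset, complementing the model-based
#' [peak_speed()]: saccadic refixations reach speeds the fitted
#' logistic underestimates.
#'
#' @param trace a [gaze_trace()].
#' @return max |central-difference velocity| after onset (deg/s).
#' @export
raw_peak_speed <- function(trace) {
  dev <- deviation_signal(trace)
  post <- trace$time_s > 0 & !is.na(dev)
  y <- dev[post]; t <- trace$time_s[post]
  n <- length(y)
  if (n < 3L) return(NA_real_)
  max(abs((y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])))
}

#' Compute the full set of per-trial deviation metrics
#'
#' Fits the logistic model (unless a fit is supplied) and assembles the
#' deviation angle (degrees and prism diopters), peak deviation speed,
#' stabilization time, overshoot depth and category, maximum deviation,
#' rebound-saccade flag and the auxiliary raw speed.
#'
#' @param trace a [gaze_trace()].
#' @param fit optional precomputed [fit_logistic()] result.
#' @param saccade_threshold_deg_s threshold for rebound-saccade
#'   detection (deg/s).
#' @param window_pre_s,window_post_s fit window (s), used when `fit` is
#'   not supplied.
#' @return object of class `deviation_metrics` (a named list); the fit
#'   is attached as attribute `"fit"`.
#' @export
trace_metrics <- function(trace, fit = NULL, saccade_threshold_deg_s = 30,
                          window_pre_s = 10, window_post_s = 10) {
  if (is.null(fit)) fit <- fit_logistic(trace, window_pre_s, window_post_s)
  stop_if_not_converged(fit)
  ov <- overshoot_depth(trace, fit)
  m <- list(angle_deg = fit$deviation_a_deg,
            angle_pd = deg_to_pd(fit$deviation_a_deg),
            peak_speed_deg_s = peak_speed(fit),
            raw_peak_speed_deg_s = raw_peak_speed(trace),
            stabilization_time_s = stabilization_time(fit),
            overshoot_depth_deg = ov$depth_deg,
            overshoot_category = classify_overshoot(ov$depth_deg),
            max_deviation_deg = ov$max_deviation_deg,
            rebound_saccade = detect_rebound_saccade(
              trace, threshold_deg_s = saccade_threshold_deg_s))
  class(m) <- "deviation_metrics"
  attr(m, "fit") <- fit
  m
}

#' @export
print.deviation_metrics <- function(x, ...) {
  cat(sprintf(
    "<deviation_metrics> angle %.2f deg (%.2f PD), peak speed %.2f deg/s\n",
    x$angle_deg, x$angle_pd, x$peak_speed_deg_s))
  cat(sprintf(
    "  stabilization %.2f s, overshoot %.2f deg (%s), rebound-saccade: %s\n",
    x$stabilization_time_s, x$overshoot_depth_deg, x$overshoot_category,
    x$rebound_saccade))
  invisible(x)
}
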