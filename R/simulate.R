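#' Parameters for a simulated phoric (latent-deviation) trace
#'
#' Describes the forward model of a covered-eye drift under occlusion:
#' a logistic approach to the fusion-free position, an optional
#' overshoot transient, Gaussian measurement noise and blink dropouts.
#'
#' @param baseline_deg pre-occlusion covered-eye position (deg).
#' @param deviation_deg signed asymptote shift `a` (deg); exodeviation
#'   negative.
#' @param rate_per_s logistic steepness `k` (1/s), > 0.
#' @param midpoint_s logistic midpoint `t0` (s after occlusion onset).
#' @param overshoot_amp_deg amplitude of the overshoot transient (deg,
#'   >= 0); the covered eye transiently goes this far beyond its final
#'   asymptote.
#' @param overshoot_decay_s decay constant of the transient (s, > 0);
#'   the transient peaks `overshoot_decay_s` after `midpoint_s`.
#' @param noise_sd_deg SD of iid Gaussian measurement noise (deg, >= 0).
#' @param blink_prob per-sample dropout probability in `[0, 1)`.
#' @param fs_hz sampling rate (Hz), default 30.
#' @param pre_s,post_s window half-lengths before/after onset (s),
#'   default 10 each.
#' @param seed RNG seed for this trace.
#' @return a named list of class `phoria_params`.
#' @export
phoria_params <- function(baseline_deg = 0, deviation_deg = -6,
                          rate_per_s = 2, midpoint_s = 1.5,
                          overshoot_amp_deg = 0, overshoot_decay_s = 2,
                          noise_sd_deg = 0.2, blink_prob = 0.01,
                          fs_hz = 30, pre_s = 10, post_s = 10,
                          seed = 1L) {
  p <- list(baseline_deg = baseline_deg, deviation_deg = deviation_deg,
            rate_per_s = rate_per_s, midpoint_s = midpoint_s,
            overshoot_amp_deg = overshoot_amp_deg,
            overshoot_decay_s = overshoot_decay_s,
            noise_sd_deg = noise_sd_deg, blink_prob = blink_prob,
            fs_hz = fs_hz, pre_s = pre_s, post_s = post_s, seed = seed)
  if (!is.finite(p$rate_per_s) || p$rate_per_s <= 0) {
    stop("`rate_per_s` must be > 0", call. = FALSE)
  }
  if (!is.finite(p$fs_hz) || p$fs_hz <= 0) {
    stop("`fs_hz` must be > 0", call. = FALSE)
  }
  if (!is.finite(p$blink_prob) || p$blink_prob < 0 || p$blink_prob >= 1) {
    stop("`blink_prob` must be in [0, 1)", call. = FALSE)
  }
  if (!is.finite(p$overshoot_amp_deg) || p$overshoot_amp_deg < 0) {
    stop("`overshoot_amp_deg` must be >= 0", call. = FALSE)
  }
  if (!is.finite(p$overshoot_decay_s) || p$overshoot_decay_s <= 0) {
    stop("`overshoot_decay_s` must be > 0", call. = FALSE)
  }
  if (!is.finite(p$noise_sd_deg) || p$noise_sd_deg < 0) {
    stop("`noise_sd_deg` must be >= 0", call. = FALSE)
  }
  class(p) <- "phoria_params"
  p
}

#' Noise-free forward model of a phoric trace (deviation coordinates)
#'
#' Evaluates baseline + a/(1 + exp(-k (t - t0))) plus the overshoot
#' transient at the given times. The transient is a single-extremum
#' pulse amp * ((t - t0)/tau) * exp(1 - (t - t0)/tau) for t > t0,
#' pointing in the deviation direction (its peak, of height amp, falls
#' at t0 + tau).
#'
#' @param t times (s, onset at 0).
#' @param params a [phoria_params()].
#' @return numeric vector of noiseless covered-eye deviation values (deg).
#' @export
phoria_model <- function(t, params) {
  a <- params$deviation_deg
  core <- params$baseline_deg + a * stats::plogis(params$rate_per_s * (t - params$midpoint_s))
  if (params$overshoot_amp_deg > 0) {
    s <- if (a != 0) sign(a) else -1
    u <- (t - params$midpoint_s) / params$overshoot_decay_s
    pulse <- ifelse(u > 0, s * params$overshoot_amp_deg * u * exp(1 - u), 0)
    core <- core + pulse
  }
  core
}

#' Analytic ground-truth metrics implied by phoric parameters
#' @noRd
phoria_ground_truth <- function(params) {
  a <- params$deviation_deg
  k <- params$rate_per_s
  list(model = "phoria",
       baseline_deg = params$baseline_deg,
       deviation_a_deg = a,
       rate_k_per_s = k,
       midpoint_t0_s = params$midpoint_s,
       angle_deg = a,
       peak_speed_deg_s = abs(a) * k / 4,
       stabilization_time_s = params$midpoint_s + log(9) / k,
       overshoot_depth_deg = params$overshoot_amp_deg)
}

#' Simulate one phoric cover-test trace
#'
#' Generates a two-eye gaze trace in which the covered eye drifts
#' sigmoidally from its baseline to the fusion-free position while the
#' fixating eye holds the target. The covered eye is the left one, so
#' an exodeviation (negative `deviation_deg`) appears as a leftward
#' (negative) drift of the covered-eye channel and the deviation signal
#' carries the same sign. Ground-truth parameters and analytic metrics
#' are attached for recovery testing.
#'
#' @param params a [phoria_params()].
#' @return a [gaze_trace()] with `ground_truth` attached.
#' @export
simulate_phoria_trace <- function(params) {
  if (!inherits(params, "phoria_params")) params <- do.call(phoria_params, params)
  fs <- params$fs_hz
  t <- seq(-params$pre_s, params$post_s, by = 1 / fs)
  clean <- phoria_model(t, params)
  with_seed(params$seed, {
    n <- length(t)
    covered <- clean + stats::rnorm(n, 0, params$noise_sd_deg)
    fixating <- stats::rnorm(n, 0, params$noise_sd_deg)
    miss <- if (params$blink_prob > 0) {
      stats::runif(n) < params$blink_prob
    } else {
      rep(FALSE, n)
    }
    covered[miss] <- NA_real_
    fixating[miss] <- NA_real_
    gaze_trace(time_s = t, fixating_deg = fixating, covered_deg = covered,
               covered_eye_side = "left", fs_hz = fs, missing = miss,
               ground_truth = c(phoria_ground_truth(params),
                                list(params = unclass(params))))
  })
}

#' Parameters for a simulated tropic (manifest-deviation) trace
#'
#' Describes a refixation event: before occlusion the soon-to-be-covered
#' (right) eye fixates while the fellow eye rests at its manifest
#' deviation; at onset the fellow eye takes up fixation with a saccade,
#' optionally overshooting and correcting back with a rebound-saccade,
#' while the covered eye moves conjugately and settles at the
#' fusion-free deviation.
#'
#' @param pre_deviation_deg manifest deviation of the non-fixating eye
#'   before occlusion (deg, exo negative); must be nonzero.
#' @param saccade_peak_speed_deg_s peak speed of the refixation saccade
#'   (deg/s, > 0).
#' @param rebound_amp_deg amplitude of the corrective rebound-saccade
#'   (deg, >= 0); 0 disables it.
#' @param final_deviation_deg covered-eye deviation after stabilization
#'   (deg, exo negative).
#' @param noise_sd_deg Gaussian noise SD (deg).
#' @param fs_hz sampling rate (Hz).
#' @param pre_s,post_s window half-lengths (s).
#' @param seed RNG seed.
#' @return a named list of class `tropia_params`.
#' @export
tropia_params <- function(pre_deviation_deg = -17,
                          saccade_peak_speed_deg_s = 90,
                          rebound_amp_deg = 3,
                          final_deviation_deg = -17,
                          noise_sd_deg = 0.2, fs_hz = 30,
                          pre_s = 10, post_s = 10, seed = 1L) {
  p <- list(pre_deviation_deg = pre_deviation_deg,
            saccade_peak_speed_deg_s = saccade_peak_speed_deg_s,
            rebound_amp_deg = rebound_amp_deg,
            final_deviation_deg = final_deviation_deg,
            noise_sd_deg = noise_sd_deg, fs_hz = fs_hz,
            pre_s = pre_s, post_s = post_s, seed = seed)
  if (!is.finite(p$saccade_peak_speed_deg_s) || p$saccade_peak_speed_deg_s <= 0) {
    stop("`saccade_peak_speed_deg_s` must be > 0", call. = FALSE)
  }
  if (!is.finite(p$fs_hz) || p$fs_hz <= 0) stop("`fs_hz` must be > 0", call. = FALSE)
  if (!is.finite(p$pre_deviation_deg) || p$pre_deviation_deg == 0) {
    stop("`pre_deviation_deg` must be nonzero (a tropia is manifest before occlusion)",
         call. = FALSE)
  }
  if (!is.finite(p$rebound_amp_deg) || p$rebound_amp_deg < 0) {
    stop("`rebound_amp_deg` must be >= 0", call. = FALSE)
  }
  class(p) <- "tropia_params"
  p
}

# Cumulative displacement of a raised-cosine-velocity saccade:
# v(t) = vp/2 * (1 - cos(2 pi (t - t_on) / dur)) over [t_on, t_on + dur],
# amplitude = vp * dur / 2. Returns displacement in [0, amp].
saccade_displacement <- function(t, t_on, amp, dur) {
  u <- (t - t_on) / dur
  u <- pmin(pmax(u, 0), 1)
  amp * (u - sin(2 * pi * u) / (2 * pi))
}

#' Simulate one tropic cover-test trace
#'
#' @param params a [tropia_params()].
#' @return a [gaze_trace()] (covered eye: right) with `ground_truth`
#'   attached. A warning is raised (and the trace still emitted) when
#'   the main saccade is too fast to be resolved at the sampling rate
#'   (duration under two sample intervals).
#' @export
simulate_tropia_trace <- function(params) {
  if (!inherits(params, "tropia_params")) params <- do.call(tropia_params, params)
  fs <- params$fs_hz
  t <- seq(-params$pre_s, params$post_s, by = 1 / fs)
  pre <- params$pre_deviation_deg
  vp <- params$saccade_peak_speed_deg_s
  reb <- params$rebound_amp_deg

  # refixating (fellow) eye: pre -> target1 (-> 0 if rebound)
  dir <- sign(0 - pre)
  target1 <- dir * reb              # overshoot past the fixation point
  a1 <- abs(target1 - pre)
  d1 <- 2 * a1 / vp                 # raised-cosine: amp = vp * dur / 2
  latency <- 0.1                    # refixation latency after onset (s)
  isi <- 0.15                       # intersaccadic interval (s)
  if (d1 < 2 / fs) {
    warning(sprintf(
      "saccade duration %.3f s is under two sample intervals at %g Hz; profile undersampled",
      d1, fs), call. = FALSE)
  }
  fix_clean <- pre + dir * saccade_displacement(t, latency, a1, d1)
  if (reb > 0) {
    d2 <- 2 * reb / vp              # corrective saccade: same peak speed
    fix_clean <- fix_clean - dir * saccade_displacement(t, latency + d1 + isi, reb, d2)
  }
  # covered (right) eye follows the same normalized trajectory, scaled to
  # its own endpoint (conjugate movement). Deviation = -(covered - fixating)
  # for a covered right eye, so the endpoint in absolute coordinates is
  # -final_deviation.
  w <- (fix_clean - pre) / (0 - pre)
  cov_clean <- (-params$final_deviation_deg) * w

  with_seed(params$seed, {
    n <- length(t)
    fixating <- fix_clean + stats::rnorm(n, 0, params$noise_sd_deg)
    covered <- cov_clean + stats::rnorm(n, 0, params$noise_sd_deg)
    gaze_trace(time_s = t, fixating_deg = fixating, covered_deg = covered,
               covered_eye_side = "right", fs_hz = fs,
               ground_truth = list(model = "tropia",
                                   angle_deg = params$final_deviation_deg,
                                   peak_speed_deg_s = vp,
                                   rebound_saccade = reb > 0,
                                   params = unclass(params)))
  })
}

#' Configuration for a simulated phoric cohort
#'
#' Defaults emulate a small exophoric cohort measured with near-target
#' video-oculography: deviation magnitudes 2-10 deg, logistic rates
#' coupled to the deviation magnitude (larger deviations move faster),
#' roughly half the subjects with an overshoot above 0.5 deg, and an
#' alternate prism cover test (APCT) value offset toward less exo than
#' the device measurement.
#'
#' @param n_subjects number of subjects (>= 2), default 13.
#' @param deviation_range_deg length-2 positive increasing range of
#'   deviation magnitudes |a| (deg).
#' @param speed_coupling exponent linking the logistic rate k to |a|
#'   (k proportional to |a|^speed_coupling); > 0 makes larger deviations
#'   faster.
#' @param overshoot_frac fraction of subjects with overshoot amplitude
#'   above 0.5 deg.
#' @param noise_sd_deg measurement noise SD (deg).
#' @param apct_offset_pd systematic APCT-minus-device offset (PD);
#'   positive means the APCT reads less exo than the device.
#' @param blink_prob per-sample dropout probability.
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @return a named list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 13,
                          deviation_range_deg = c(2, 10),
                          speed_coupling = 1,
                          overshoot_frac = 7 / 13,
                          noise_sd_deg = 0.2,
                          apct_offset_pd = 4.5,
                          blink_prob = 0.01,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              deviation_range_deg = deviation_range_deg,
              speed_coupling = speed_coupling,
              overshoot_frac = overshoot_frac,
              noise_sd_deg = noise_sd_deg,
              apct_offset_pd = apct_offset_pd,
              blink_prob = blink_prob,
              seed = seed)
  if (cfg$n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  r <- cfg$deviation_range_deg
  if (length(r) != 2L || !all(is.finite(r)) || r[1] <= 0 || r[2] <= r[1]) {
    stop("`deviation_range_deg` must be positive and increasing", call. = FALSE)
  }
  if (cfg$overshoot_frac < 0 || cfg$overshoot_frac > 1) {
    stop("`overshoot_frac` must be in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' One cohort subject: trace plus clinical metadata
#'
#' @param subject_id identifier string.
#' @param diagnosis `"exophoria"`, `"intermittent_exotropia"` or
#'   `"exotropia"`.
#' @param apct_pd alternate prism cover test value (PD, exo negative).
#' @param trace a [gaze_trace()].
#' @param metrics optional [deviation_metrics] once computed.
#' @return an object of class `cohort_record`.
#' @export
cohort_record <- function(subject_id, diagnosis, apct_pd, trace,
                          metrics = NULL) {
  diagnosis <- match.arg(diagnosis,
                         c("exophoria", "intermittent_exotropia", "exotropia"))
  if (!is.finite(apct_pd)) stop("`apct_pd` must be finite", call. = FALSE)
  stopifnot(inherits(trace, "gaze_trace"))
  structure(list(subject_id = subject_id, diagnosis = diagnosis,
                 apct_pd = apct_pd, trace = trace, metrics = metrics),
            class = "cohort_record")
}

#' Simulate a phoric cohort with coupled per-subject parameters
#'
#' Draws per-subject deviation magnitudes uniformly over
#' `deviation_range_deg` (all exo, hence negative angles), couples the
#' logistic rate to the magnitude via `k = 2 (|a|/6)^speed_coupling`
#' times lognormal jitter, couples the overshoot amplitude to the
#' implied peak speed through a Gaussian copula (so faster deviations
#' overshoot deeper), and sets the APCT value to the per-subject
#' degree-to-PD conversion plus `apct_offset_pd` plus 2 PD of
#' measurement noise. Fully reproducible from `seed`.
#'
#' @param config a [cohort_config()].
#' @return list of [cohort_record()] objects (all diagnosis
#'   `"exophoria"`), each trace carrying its analytic ground truth.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_subjects
  with_seed(config$seed, {
    mag <- stats::runif(n, config$deviation_range_deg[1], config$deviation_range_deg[2])
    a <- -mag
    k <- 2 * (mag / 6)^config$speed_coupling * exp(stats::rnorm(n, 0, 0.25))
    k <- pmin(pmax(k, 0.1), 50)
    t0 <- stats::runif(n, 0.8, 2.2)
    speed <- mag * k / 4
    # overshoot amplitude: two-part distribution with P(amp > 0.5) =
    # overshoot_frac, rank-coupled to peak speed (Gaussian copula, rho 0.8)
    rho <- 0.8
    z_speed <- stats::qnorm((rank(speed, ties.method = "first") - 0.5) / n)
    u <- stats::pnorm(rho * z_speed + sqrt(1 - rho^2) * stats::rnorm(n))
    q <- 1 - config$overshoot_frac
    amp <- ifelse(u <= q,
                  0.5 * u / q,                     # U(0, 0.5) branch
                  0.5 + 1.0 * (u - q) / (1 - q))   # U(0.5, 1.5) branch
    apct <- deg_to_pd(a) + config$apct_offset_pd + stats::rnorm(n, 0, 2)
    sub_seed <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      p <- phoria_params(baseline_deg = 0, deviation_deg = a[i],
                         rate_per_s = k[i], midpoint_s = t0[i],
                         overshoot_amp_deg = amp[i],
                         overshoot_decay_s = 2,
                         noise_sd_deg = config$noise_sd_deg,
                         blink_prob = config$blink_prob,
                         seed = sub_seed[i])
      tr <- simulate_phoria_trace(p)
      tr$subject_id <- sprintf("S%02d", i)
      tr$diagnosis <- "exophoria"
      tr$apct_pd <- apct[i]
      cohort_record(subject_id = tr$subject_id, diagnosis = "exophoria",
                    apct_pd = apct[i], trace = tr)
    })
  })
}
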