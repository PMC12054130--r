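test_that("the deviation signal follows the exo-negative sign convention", {
  # covered right eye 2 deg temporal (rightward) of the fixating eye: exo, -2
  tr <- tiny_trace(covered_offset_deg = 2, side = "right")
  expect_equal(deviation_signal(tr), rep(-2, 4))
  # covered left eye 2 deg rightward is nasal for the left eye: eso, +2
  tl <- tiny_trace(covered_offset_deg = 2, side = "left")
  expect_equal(deviation_signal(tl), rep(2, 4))
  # identical series give zero deviation
  t0 <- tiny_trace(covered_offset_deg = 0)
  expect_equal(deviation_signal(t0), rep(0, 4))
  # missing samples propagate
  tm <- tiny_trace(covered_offset_deg = 2)
  tm$missing[2] <- TRUE
  expect_true(is.na(deviation_signal(tm)[2]))
  expect_false(anyNA(deviation_signal(tm)[-2]))
})

test_that("noise-free synthetic traces are recovered to machine-level accuracy", {
  for (prm in list(c(-6, 2, 1.5), c(-2, 20, 1.0), c(-10, 0.3, 2.0))) {
    p <- clean_phoria(deviation_deg = prm[1], rate_per_s = prm[2],
                      midpoint_s = prm[3])
    f <- fit_logistic(simulate_phoria_trace(p))
    expect_true(f$converged)
    expect_lt(abs(f$baseline_deg), 1e-6)
    expect_lt(abs(f$deviation_a_deg - prm[1]), 1e-6)
    expect_lt(abs(f$rate_k_per_s - prm[2]), 1e-6)
    expect_lt(abs(f$midpoint_t0_s - prm[3]), 1e-6)
    # the four metrics match their analytic ground truth
    expect_lt(abs(peak_speed(f) - abs(prm[1]) * prm[2] / 4), 1e-6)
    expect_lt(abs(stabilization_time(f) - (prm[3] + log(9) / prm[2])), 1e-6)
    tr <- simulate_phoria_trace(p)
    expect_equal(overshoot_depth(tr, f)$depth_deg, 0)
  }
})

test_that("fits on deviation-free noise carry a small-deviation warning", {
  warned <- 0L
  a_hat <- numeric(100)
  realized <- numeric(100)
  for (s in 1:100) {
    t <- seq(-10, 10, by = 1 / 30)
    set.seed(s)
    tr <- gaze_trace(t, rnorm(length(t), 0, 0.1), rnorm(length(t), 0, 0.1),
                     covered_eye_side = "left", fs_hz = 30)
    w <- FALSE
    f <- withCallingHandlers(
      fit_logistic(tr),
      warning = function(cnd) {
        if (grepl("small-deviation", conditionMessage(cnd))) w <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (w || isTRUE(f$small_deviation)) warned <- warned + 1L
    a_hat[s] <- f$deviation_a_deg
    realized[s] <- abs(predict_logistic(f, 10) - predict_logistic(f, -10))
  }
  expect_gte(warned, 95)
  # the apparent deviation measured within the window stays in the noise;
  # the raw asymptote difference can extrapolate larger on an unidentified
  # (flat) likelihood, so it is summarized by its typical size
  expect_true(all(realized < 0.4))
  expect_lt(median(abs(a_hat)), 0.4)
})

test_that("too few usable samples raise a data error", {
  t <- seq(-0.2, 10, by = 1 / 30)  # only 6 pre-onset samples
  tr <- gaze_trace(t, rnorm(length(t), 0, 0.1), rnorm(length(t), 0, 0.1),
                   fs_hz = 30)
  expect_error(fit_logistic(tr), "too few usable samples")
})

test_that("peak speed is the logistic's maximum slope", {
  p <- clean_phoria(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5)
  f <- fit_logistic(simulate_phoria_trace(p))
  expect_equal(peak_speed(f), 3.0, tolerance = 1e-9)
  # numeric-differentiation oracle at 1 kHz
  tt <- seq(-10, 10, by = 1e-3)
  fd <- max(abs(diff(predict_logistic(f, tt)) / 1e-3))
  expect_lt(abs(peak_speed(f) - fd) / fd, 1e-3)
  # degenerate: zero deviation has zero speed
  f0 <- f
  f0$deviation_a_deg <- 0
  expect_equal(peak_speed(f0), 0)
  # non-converged fits refuse to yield metrics
  fbad <- f
  fbad$converged <- FALSE
  expect_error(peak_speed(fbad), "converge")
  expect_error(stabilization_time(fbad), "converge")
})

test_that("stabilization time hits the 90% level exactly", {
  p <- clean_phoria(deviation_deg = -6, rate_per_s = log(9), midpoint_s = 1)
  f <- fit_logistic(simulate_phoria_trace(p))
  expect_equal(stabilization_time(f), 2.0, tolerance = 1e-6)
  # step-function limit: large k collapses onto the midpoint
  p2 <- clean_phoria(deviation_deg = -6, rate_per_s = 150, midpoint_s = 0.5)
  f2 <- fit_logistic(simulate_phoria_trace(p2))
  expect_equal(stabilization_time(f2), 0.5 + log(9) / 150, tolerance = 1e-4)
  expect_lt(stabilization_time(f2) - 0.5, 0.03)
  # plug-back: |f(t*) - L0| / |a| = 0.90 to 1e-9
  for (seed in 1:5) {
    pp <- phoria_params(deviation_deg = -5, rate_per_s = 1.5, midpoint_s = 1,
                        noise_sd_deg = 0.2, blink_prob = 0, seed = seed)
    ff <- suppressWarnings(fit_logistic(simulate_phoria_trace(pp)))
    t_star <- stabilization_time(ff)
    ratio <- abs(predict_logistic(ff, t_star) - ff$baseline_deg) /
      abs(ff$deviation_a_deg)
    expect_lt(abs(ratio - 0.9), 1e-9)
  }
  # already past 90% at onset: clamp to zero with a warning
  fpast <- f
  fpast$midpoint_t0_s <- -5
  expect_warning(ts <- stabilization_time(fpast), "already")
  expect_equal(ts, 0)
})

test_that("overshoot depth recovers constructed transients and floors at zero", {
  # monotone noise-free trace: depth exactly 0
  p <- clean_phoria(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5)
  tr <- simulate_phoria_trace(p)
  f <- fit_logistic(tr)
  ov <- overshoot_depth(tr, f)
  expect_equal(ov$depth_deg, 0)
  expect_lt(abs(ov$max_deviation_deg - (-6)), 0.01)
  # constructed transient of 1.2 deg
  p2 <- clean_phoria(deviation_deg = -6, rate_per_s = 6, midpoint_s = 1,
                     overshoot_amp_deg = 1.2, overshoot_decay_s = 1)
  tr2 <- simulate_phoria_trace(p2)
  f2 <- fit_logistic(tr2)
  d2 <- overshoot_depth(tr2, f2)$depth_deg
  expect_gt(d2, 1.1)
  expect_lt(d2, 1.3)
})

test_that("the overshoot noise floor sits near half a degree at 0.2 deg noise", {
  # Monte-Carlo calibration of the depth estimator on transient-free
  # noisy traces; the measured floor (median ~0.5 deg) is a property of
  # taking an extremum over ~300 smoothed samples
  dep <- vapply(1:200, function(s) {
    p <- phoria_params(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5,
                       noise_sd_deg = 0.2, blink_prob = 0, seed = s)
    tr <- simulate_phoria_trace(p)
    f <- suppressWarnings(fit_logistic(tr))
    overshoot_depth(tr, f)$depth_deg
  }, numeric(1))
  expect_gt(median(dep), 0.40)
  expect_lt(median(dep), 0.60)
})

test_that("overshoot categories follow the clinical thresholds", {
  expect_equal(classify_overshoot(0.7), "mid")
  expect_equal(classify_overshoot(0.0), "lt0p5")
  expect_equal(classify_overshoot(0.49), "lt0p5")
  expect_equal(classify_overshoot(0.5), "mid")
  expect_equal(classify_overshoot(1.0), "mid")
  expect_equal(classify_overshoot(1.0001), "gt1")
  expect_error(classify_overshoot(-0.1), "nonnegative")
})

test_that("rebound-saccades are detected only in tropic refixation", {
  expect_true(detect_rebound_saccade(
    simulate_tropia_trace(tropia_params(rebound_amp_deg = 3, seed = 1))))
  expect_false(detect_rebound_saccade(
    simulate_tropia_trace(tropia_params(rebound_amp_deg = 0, seed = 1))))
  # phoric drift speeds never reach the saccadic threshold
  p <- phoria_params(deviation_deg = -8, rate_per_s = 2, seed = 1)  # 4 deg/s
  expect_false(detect_rebound_saccade(simulate_phoria_trace(p)))
})

test_that("stabilization shortens with rate and speed grows with magnitude", {
  ks <- c(0.5, 1, 2, 4, 8)
  stab <- vapply(ks, function(k) {
    f <- fit_logistic(simulate_phoria_trace(
      clean_phoria(deviation_deg = -6, rate_per_s = k, midpoint_s = 1.5)))
    stabilization_time(f)
  }, numeric(1))
  expect_true(all(diff(stab) < 0))
  as_ <- c(-2, -4, -6, -8, -10)
  spd <- vapply(as_, function(a) {
    f <- fit_logistic(simulate_phoria_trace(
      clean_phoria(deviation_deg = a, rate_per_s = 2, midpoint_s = 1.5)))
    peak_speed(f)
  }, numeric(1))
  expect_true(all(diff(spd) > 0))
})

test_that("negating both eye series flips signed metrics only", {
  p <- phoria_params(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5,
                     overshoot_amp_deg = 0.8, noise_sd_deg = 0.1,
                     blink_prob = 0, seed = 7)
  tr <- simulate_phoria_trace(p)
  neg <- tr
  neg$fixating_deg <- -tr$fixating_deg
  neg$covered_deg <- -tr$covered_deg
  f <- suppressWarnings(fit_logistic(tr))
  fn <- suppressWarnings(fit_logistic(neg))
  expect_equal(fn$deviation_a_deg, -f$deviation_a_deg, tolerance = 1e-6)
  expect_equal(peak_speed(fn), peak_speed(f), tolerance = 1e-6)
  expect_equal(stabilization_time(fn), stabilization_time(f), tolerance = 1e-6)
  ov <- overshoot_depth(tr, f)
  ovn <- overshoot_depth(neg, fn)
  expect_equal(ovn$depth_deg, ov$depth_deg, tolerance = 1e-6)
  expect_equal(ovn$max_deviation_deg, -ov$max_deviation_deg, tolerance = 1e-6)
})

test_that("trace_metrics bundles all per-trial statistics coherently", {
  p <- phoria_params(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5,
                     seed = 8)
  m <- suppressWarnings(trace_metrics(simulate_phoria_trace(p)))
  expect_s3_class(m, "deviation_metrics")
  expect_equal(m$angle_pd, deg_to_pd(m$angle_deg))
  expect_equal(m$overshoot_category, classify_overshoot(m$overshoot_depth_deg))
  expect_false(m$rebound_saccade)
  expect_gt(m$raw_peak_speed_deg_s, 0)
})
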