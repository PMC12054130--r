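test_that("noise-free phoria traces equal the logistic forward model pointwise", {
  p <- clean_phoria(deviation_deg = -6, rate_per_s = 2, midpoint_s = 1.5)
  tr <- simulate_phoria_trace(p)
  expected <- -6 / (1 + exp(-2 * (tr$time_s - 1.5)))
  expect_lt(max(abs(tr$covered_deg - expected)), 1e-12)
  expect_true(all(tr$fixating_deg == 0))
  # window coverage: at least pre_s*fs samples before and post_s*fs after onset
  expect_gte(sum(tr$time_s < 0), 10 * 30)
  expect_gte(sum(tr$time_s > 0), 10 * 30)
})

test_that("analytic ground truth accompanies every simulated phoria trace", {
  p <- clean_phoria(deviation_deg = -4, rate_per_s = 3, midpoint_s = 1,
                    overshoot_amp_deg = 0.8)
  gt <- simulate_phoria_trace(p)$ground_truth
  expect_equal(gt$angle_deg, -4)
  expect_equal(gt$peak_speed_deg_s, 4 * 3 / 4)
  expect_equal(gt$stabilization_time_s, 1 + log(9) / 3)
  expect_equal(gt$overshoot_depth_deg, 0.8)
})

test_that("measurement noise has the configured amplitude", {
  resids <- unlist(lapply(1:100, function(s) {
    p <- phoria_params(noise_sd_deg = 0.2, blink_prob = 0, seed = s)
    tr <- simulate_phoria_trace(p)
    tr$covered_deg - phoria_model(tr$time_s, p)
  }))
  expect_gt(sd(resids), 0.15)
  expect_lt(sd(resids), 0.25)
})

test_that("the overshoot transient reaches its constructed extremum", {
  # pulse peaks after the logistic has essentially saturated, so the
  # post-onset minimum sits one amplitude beyond the asymptote
  p <- clean_phoria(deviation_deg = -6, rate_per_s = 12, midpoint_s = 1.5,
                    overshoot_amp_deg = 1, overshoot_decay_s = 0.5)
  tr <- simulate_phoria_trace(p)
  m <- min(deviation_signal(tr)[tr$time_s > 0])
  expect_lt(abs(m - (-7)), 0.05)
  # before the midpoint the pulse is identically zero
  pre <- tr$time_s <= 1.5
  expect_equal(tr$covered_deg[pre],
               -6 / (1 + exp(-12 * (tr$time_s[pre] - 1.5))), tolerance = 1e-12)
})

test_that("blink dropouts are flagged missing at the configured rate", {
  frac <- vapply(1:20, function(s) {
    # ~1000-sample traces
    p <- phoria_params(blink_prob = 0.05, pre_s = 16.65, post_s = 16.65,
                       seed = s)
    mean(simulate_phoria_trace(p)$missing)
  }, numeric(1))
  n <- 1000
  expect_true(all(abs(frac - 0.05) < 3 * sqrt(0.05 * 0.95 / n)))
  # dropout samples carry NA gaze, never zeros
  p <- phoria_params(blink_prob = 0.2, seed = 2)
  tr <- simulate_phoria_trace(p)
  expect_true(all(is.na(tr$covered_deg[tr$missing])))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(phoria_params(rate_per_s = 0), "rate_per_s")
  expect_error(phoria_params(blink_prob = 1), "blink_prob")
  expect_error(phoria_params(overshoot_amp_deg = -1), "overshoot_amp_deg")
  expect_error(phoria_params(fs_hz = 0), "fs_hz")
  expect_error(tropia_params(saccade_peak_speed_deg_s = -5), "peak_speed")
  expect_error(tropia_params(pre_deviation_deg = 0), "pre_deviation")
})

test_that("tropia refixation speed matches the requested peak", {
  tr <- simulate_tropia_trace(tropia_params(saccade_peak_speed_deg_s = 90,
                                            noise_sd_deg = 0))
  v <- diff(tr$fixating_deg) * tr$fs_hz
  expect_gte(max(abs(v)), 81)
  expect_lte(max(abs(v)), 99)
})

test_that("tropia without a rebound approaches fixation monotonically", {
  tr <- simulate_tropia_trace(tropia_params(rebound_amp_deg = 0,
                                            noise_sd_deg = 0))
  post <- tr$fixating_deg[tr$time_s > 0]
  expect_true(all(diff(post) >= -1e-9))
  expect_lt(abs(post[length(post)]), 1e-9)
})

test_that("the covered eye of a tropia settles at the final deviation", {
  tr <- simulate_tropia_trace(tropia_params(pre_deviation_deg = -17,
                                            final_deviation_deg = -17,
                                            seed = 4))
  f <- suppressWarnings(fit_logistic(tr))
  expect_lt(abs((f$baseline_deg + f$deviation_a_deg) - (-17)), 0.2)
  # the manifest deviation is present before occlusion too
  dev_pre <- deviation_signal(tr)[tr$time_s < 0]
  expect_lt(abs(mean(dev_pre) - (-17)), 0.1)
})

test_that("an undersampled saccade warns but still yields a trace", {
  p <- tropia_params(saccade_peak_speed_deg_s = 700, noise_sd_deg = 0)
  expect_warning(tr <- simulate_tropia_trace(p), "undersampled")
  expect_s3_class(tr, "gaze_trace")
})

test_that("cohorts have the requested size and are seed-reproducible", {
  recs <- simulate_cohort(cohort_config(n_subjects = 13, seed = 11))
  expect_length(recs, 13)
  expect_true(all(vapply(recs, function(r) r$diagnosis, "") == "exophoria"))
  recs2 <- simulate_cohort(cohort_config(n_subjects = 13, seed = 11))
  expect_identical(recs, recs2)
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(deviation_range_deg = c(5, 2)), "deviation_range")
})

test_that("speed coupling makes larger deviations faster in ground truth", {
  # signed angle vs analytic peak speed: negative correlation expected
  # (exo angles are negative, larger magnitudes move faster)
  neg <- vapply(1:20, function(s) {
    recs <- simulate_cohort(cohort_config(n_subjects = 50, speed_coupling = 1,
                                          noise_sd_deg = 0.1, seed = s))
    a <- vapply(recs, function(r) r$trace$ground_truth$angle_deg, numeric(1))
    b <- vapply(recs, function(r) r$trace$ground_truth$peak_speed_deg_s, numeric(1))
    cor(a, b, method = "spearman") < 0
  }, logical(1))
  expect_true(all(neg))
})
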