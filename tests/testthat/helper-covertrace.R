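# shared fixtures and independent oracles, built in code at test time

# noiseless phoria parameter set used across tests
clean_phoria <- function(...) {
  phoria_params(noise_sd_deg = 0, blink_prob = 0, ...)
}

# literal enumeration of all permutations of a vector (independent oracle
# for the exact Spearman test; only usable for small n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# brute-force two-sided exact Spearman p-value by full n! enumeration
brute_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rs_obs <- cor(rx, ry)
  rs_all <- vapply(all_perms(sort(ry)), function(p) cor(rx, p), numeric(1))
  mean(abs(rs_all) >= abs(rs_obs) - 1e-9)
}

# a small hand-built trace straddling onset, uniform at 30 Hz
tiny_trace <- function(covered_offset_deg = 0, side = "right", n_pre = 2,
                       n_post = 2, fs = 30) {
  t <- seq(-n_pre, n_post - 1) / fs + 1 / (2 * fs)
  gaze_trace(time_s = t,
             fixating_deg = rep(0, length(t)),
             covered_deg = rep(covered_offset_deg, length(t)),
             covered_eye_side = side, fs_hz = fs)
}
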