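# Shared fixtures: a flat-rate pair whose units fire at exactly 12 pps
# whenever active, so normalised rates sit at 1.0 with unit gains, and a
# fast buffer config used where wall time matters.

flat_pair <- function(theta_on = c(3, 4), theta_off = c(2.5, 1.5),
                      isi_cov = 0) {
  pool_from_params(theta_on = theta_on, theta_off = theta_off,
                   r_min = 12, rate_gain = 0, r_sat = 12, isi_cov = isi_cov)
}

# Rate model evaluated independently of the simulator internals.
unit_rate_for_test <- function(pool, d) {
  pmin(pool$r_sat, pmax(pool$r_min,
                        pool$r_min + pool$rate_gain * (d - pool$theta_on)))
}

# Constant-level trace over [t0, t1] (for renewal and window tests).
new_trace_for_test <- function(t0, t1, level, fs) {
  t <- seq(t0, t1, by = 1 / fs)
  out <- tibble::tibble(time_s = t, value = rep(level, length(t)))
  attr(out, "fs") <- fs
  class(out) <- unique(c("mu_trace", class(out)))
  out
}

# Cursor stream with positions supplied directly (for metric tests).
stream_from_xy <- function(x, y, cfg = buffer_config()) {
  n <- length(x)
  tibble::tibble(
    buffer = seq_len(n), t = seq_len(n) * cfg$buffer_s,
    rate1 = NA_real_, rate2 = NA_real_,
    rbar1 = NA_real_, rbar2 = NA_real_,
    u1 = x, u2 = y, x = x, y = y
  )
}

trial_from_xy <- function(x, y, target, cfg = buffer_config()) {
  run_trial(stream_from_xy(x, y, cfg), target, cfg)
}
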