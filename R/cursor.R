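#' Buffer configuration of the task engine
#'
#' The engine operates on acquisition buffers of `samples_per_buffer`
#' samples at `fs` Hz (125 ms by default). Per-buffer discharge rates are
#' averaged over the preceding `rate_window_buffers` buffers (1 s), the
#' cursor is smoothed with a `cursor_ma_buffers` moving average (750 ms),
#' and a hit requires `hold_buffers` consecutive buffers (875 ms, one buffer
#' longer than the moving average) inside the region. A trial times out
#' after `timeout_s`, and `rest_s` of silence is required between trials.
#'
#' @param samples_per_buffer Samples per acquisition buffer.
#' @param fs Acquisition sampling rate, Hz.
#' @param rate_window_buffers Rate-averaging window, buffers.
#' @param cursor_ma_buffers Cursor moving-average length, buffers.
#' @param hold_buffers Consecutive in-region buffers required for a hit.
#' @param timeout_s Trial timeout, seconds.
#' @param rest_s Inter-trial rest, seconds.
#' @return A list of class `mu_buffer_config`; `buffer_s` is the buffer
#'   duration in seconds and `timeout_buffers` the timeout in buffers.
#' @examples
#' cfg <- buffer_config()
#' cfg$buffer_s * 1000             # 125 ms
#' cfg$hold_buffers * cfg$buffer_s # 0.875 s
#' @export
buffer_config <- function(samples_per_buffer = 256, fs = 2048,
                          rate_window_buffers = 8, cursor_ma_buffers = 6,
                          hold_buffers = 7, timeout_s = 20, rest_s = 2) {
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(samples_per_buffer, "samples_per_buffer", positive = TRUE)
  cfg <- list(
    samples_per_buffer = as.integer(samples_per_buffer),
    fs = fs,
    rate_window_buffers = as.integer(rate_window_buffers),
    cursor_ma_buffers = as.integer(cursor_ma_buffers),
    hold_buffers = as.integer(hold_buffers),
    timeout_s = timeout_s,
    rest_s = rest_s
  )
  cfg$buffer_s <- samples_per_buffer / fs
  cfg$timeout_buffers <- as.integer(round(timeout_s / cfg$buffer_s))
  if (cfg$hold_buffers != cfg$cursor_ma_buffers + 1L)
    warn("hold_buffers differs from cursor_ma_buffers + 1 (the protocol relation).")
  class(cfg) <- "mu_buffer_config"
  cfg
}

#' Target and angle-wedge geometry
#'
#' The cursor space is spanned by the normalised discharge rates of the two
#' feedback MUs. Targets are discs of radius 0.1 centred at TI = (1, 0),
#' TII = (1, 1) and TIII = (0, 1). Each target is framed by an angle wedge
#' with apex at the origin and sides tangent to the target's circumcircle
#' (half-angle `asin(radius / |center|)`), cropped near the origin by a
#' circle of radius `inner_crop`. For the performance metric, `dmax` is the
#' TI-TIII centre distance for TI and TIII and the TII-origin distance for
#' TII; `phi_max` is 90 degrees for TI/TIII and 45 degrees for TII.
#'
#' @param target One of `"TI"`, `"TII"`, `"TIII"`.
#' @param radius Target radius, normalised units.
#' @param inner_crop Radius of the origin-centred crop circle.
#' @return A list of class `mu_geometry`.
#' @examples
#' target_geometry("TI")$dmax  # sqrt(2)
#' @export
target_geometry <- function(target = c("TI", "TII", "TIII"), radius = 0.1,
                            inner_crop = 0.4) {
  target <- arg_match(target)
  center <- switch(target, TI = c(1, 0), TII = c(1, 1), TIII = c(0, 1))
  cn <- sqrt(sum(center^2))
  dmax <- switch(target,
    TI = sqrt(2),        # |TI - TIII|
    TIII = sqrt(2),
    TII = sqrt(2))       # |TII - origin|
  structure(list(
    target = target,
    center = center,
    radius = radius,
    inner_crop = inner_crop,
    wedge_half_angle = asin(radius / cn) * 180 / pi,
    dmax = dmax,
    phi_max = if (target == "TII") 45 else 90
  ), class = "mu_geometry")
}

#' Per-buffer discharge rates of a spike train
#'
#' Counts spikes per acquisition buffer and divides by the buffer duration.
#' Buffer `b` covers `[(b-1) * buffer_s, b * buffer_s)`; a spike exactly on
#' a boundary belongs to the later buffer.
#'
#' @param times Discharge times, seconds (non-negative).
#' @param cfg A [buffer_config()].
#' @param horizon_s Analysis horizon, seconds (>= one buffer).
#' @return Tibble with `buffer`, `t_start`, `t_end`, `rate` (pps).
#' @export
buffer_rates <- function(times, cfg = buffer_config(), horizon_s) {
  if (horizon_s < cfg$buffer_s) abort("`horizon_s` must cover >= 1 buffer.")
  db <- cfg$buffer_s
  n_buf <- floor(horizon_s / db + 1e-9)
  idx <- floor(times / db + 1e-9) + 1
  idx <- idx[idx >= 1 & idx <= n_buf]
  counts <- tabulate(idx, nbins = n_buf)
  tibble(
    buffer = seq_len(n_buf),
    t_start = (seq_len(n_buf) - 1) * db,
    t_end = seq_len(n_buf) * db,
    rate = counts / db
  )
}

# Trailing mean of x over windows of k values ending at each position.
# init = "zero": missing history counts as zeros (full-k denominator);
# init = "truncate": mean over the values available so far.
trailing_mean <- function(x, k, init = c("truncate", "zero")) {
  init <- arg_match(init)
  n <- length(x)
  s <- cumsum(x)
  lag <- c(rep(0, min(k, n)), s[seq_len(max(0, n - k))])
  sums <- s - lag
  denom <- if (init == "zero") rep(k, n) else pmin(seq_len(n), k)
  sums / denom
}

#' Convert a pair of per-buffer rate streams into cursor positions
#'
#' Implements the feedback pipeline: per-buffer rates are averaged over the
#' preceding `rate_window_buffers` buffers (trailing window including the
#' current buffer), normalised by each unit's reference discharge rate at
#' 10% MVC, multiplied by the per-unit gain, and smoothed with a trailing
#' `cursor_ma_buffers` moving average. The cursor updates every buffer and
#' is not clamped; the space is unbounded upward.
#'
#' @param rates Tibble with columns `buffer`, `rate1`, `rate2` (pps per
#'   buffer for MU1 and MU2); see [bind_rate_pair()].
#' @param ref_rates Length-2 positive numeric, reference rates (pps).
#' @param gains Length-2 gains (dimensionless).
#' @param cfg A [buffer_config()].
#' @param init Warm-up handling: `"truncate"` (mean over available buffers,
#'   the default) or `"zero"` (zero-padded history, the idealised
#'   from-rest step response whose support is
#'   `rate_window_buffers + cursor_ma_buffers - 1` buffers).
#' @return A tibble of class `mu_cursor`: `buffer`, `t` (buffer end time),
#'   `rate1`, `rate2`, `rbar1`, `rbar2` (trailing-averaged rates, pps),
#'   `u1`, `u2` (gained normalised rates), `x`, `y` (cursor position).
#' @export
cursor_positions <- function(rates, ref_rates, gains = c(1, 1),
                             cfg = buffer_config(),
                             init = c("truncate", "zero")) {
  init <- arg_match(init)
  if (any(ref_rates <= 0)) abort("`ref_rates` must be > 0.")
  rb1 <- trailing_mean(rates$rate1, cfg$rate_window_buffers, init)
  rb2 <- trailing_mean(rates$rate2, cfg$rate_window_buffers, init)
  u1 <- gains[1] * rb1 / ref_rates[1]
  u2 <- gains[2] * rb2 / ref_rates[2]
  out <- tibble(
    buffer = rates$buffer,
    t = rates$buffer * cfg$buffer_s,
    rate1 = rates$rate1, rate2 = rates$rate2,
    rbar1 = rb1, rbar2 = rb2,
    u1 = u1, u2 = u2,
    x = trailing_mean(u1, cfg$cursor_ma_buffers, init),
    y = trailing_mean(u2, cfg$cursor_ma_buffers, init)
  )
  class(out) <- unique(c("mu_cursor", class(out)))
  out
}

#' Join two per-buffer rate streams into the engine's input
#' @param r1,r2 Tibbles from [buffer_rates()] for MU1 and MU2.
#' @return Tibble with `buffer`, `rate1`, `rate2` over the common buffers.
#' @export
bind_rate_pair <- function(r1, r2) {
  n <- min(nrow(r1), nrow(r2))
  tibble(buffer = r1$buffer[seq_len(n)],
         rate1 = r1$rate[seq_len(n)],
         rate2 = r2$rate[seq_len(n)])
}

#' Classify cursor positions into target / angle / neither
#'
#' A point is in the target when within `radius` of the centre (closed);
#' otherwise in the angle region when at least `inner_crop` from the origin
#' and within the wedge half-angle of the target direction (closed). The
#' origin itself is in neither region.
#'
#' @param x,y Cursor coordinates (vectors).
#' @param geom A [target_geometry()].
#' @return Character vector: `"target"`, `"angle"` or `"neither"`.
#' @export
point_region <- function(x, y, geom) {
  dx <- x - geom$center[1]
  dy <- y - geom$center[2]
  in_target <- sqrt(dx^2 + dy^2) <= geom$radius + 1e-12
  r <- sqrt(x^2 + y^2)
  ang <- cursor_angle(x, y, geom)
  in_wedge <- r >= geom$inner_crop - 1e-12 &
    ang <= geom$wedge_half_angle + 1e-12
  ifelse(in_target, "target", ifelse(r > 0 & in_wedge, "angle", "neither"))
}

# Absolute angle (degrees) between cursor vector and target-centre vector;
# the origin maps to phi_max by convention.
cursor_angle <- function(x, y, geom) {
  r <- sqrt(x^2 + y^2)
  cn <- sqrt(sum(geom$center^2))
  cosang <- (x * geom$center[1] + y * geom$center[2]) / (r * cn)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ifelse(r == 0, geom$phi_max, ang)
}

#' Run the trial state machine over a cursor stream
#'
#' Scans buffers from target onset (the start of the stream): a target hit
#' is granted at the `hold_buffers`-th consecutive in-target buffer and ends
#' the trial; an angle hit is granted at the `hold_buffers`-th consecutive
#' buffer inside the angle wedge (the target disc counts as inside the
#' wedge) and the trial continues; the trial times out after
#' `timeout_s`. A single trial can contain both an angle and a target hit.
#'
#' @param stream A `mu_cursor` stream starting at target onset.
#' @param target Target id (`"TI"`, `"TII"`, `"TIII"`) or a
#'   [target_geometry()].
#' @param cfg A [buffer_config()].
#' @return A list of class `mu_trial`: `target`, `stream` (sliced to the
#'   trial), `target_hit_buffer`, `angle_hit_buffer` (NA when not
#'   achieved), `outcome` (`"target_hit"`, `"timeout"` or `"truncated"`),
#'   `n_buffers`.
#' @export
run_trial <- function(stream, target, cfg = buffer_config()) {
  geom <- if (inherits(target, "mu_geometry")) target else target_geometry(target)
  n_max <- min(nrow(stream), cfg$timeout_buffers)
  region <- point_region(stream$x[seq_len(n_max)], stream$y[seq_len(n_max)], geom)
  in_target <- region == "target"
  in_wedge <- region %in% c("target", "angle")
  tgt_run <- 0L; wdg_run <- 0L
  hit_b <- NA_integer_; ang_b <- NA_integer_
  end_b <- n_max
  for (b in seq_len(n_max)) {
    tgt_run <- if (in_target[b]) tgt_run + 1L else 0L
    wdg_run <- if (in_wedge[b]) wdg_run + 1L else 0L
    if (is.na(ang_b) && wdg_run >= cfg$hold_buffers) ang_b <- b
    if (tgt_run >= cfg$hold_buffers) { hit_b <- b; end_b <- b; break }
  }
  outcome <- if (!is.na(hit_b)) "target_hit"
             else if (nrow(stream) >= cfg$timeout_buffers) "timeout"
             else "truncated"
  structure(list(
    target = geom$target,
    geometry = geom,
    stream = stream[seq_len(end_b), ],
    target_hit_buffer = hit_b,
    angle_hit_buffer = ang_b,
    outcome = outcome,
    n_buffers = end_b
  ), class = "mu_trial")
}

#' Run a full closed-loop session on a simulated pair
#'
#' Presents each target `repeats` times in seeded random order. For every
#' trial a drive profile is produced by `policy(target, pair, seed)`,
#' spike trains are simulated for the pair, converted to buffer rates and
#' cursor positions (zero-initialised, since each trial starts from rest),
#' and the trial state machine is run. Policies must start and end at zero
#' drive; the engine verifies the inter-trial rest (both rates silent for
#' `rest_s`) on the leading rest segment and trims it before target onset.
#'
#' @param pair A 2-row `mu_pool` (MU1 first).
#' @param policy Function `(target, pair, seed)` returning a `mu_trace`
#'   drive with a leading rest of at least `rest_s`; see
#'   [three_stage_drive()] and [random_drive()].
#' @param ref_rates,gains Cursor pipeline parameters (see
#'   [cursor_positions()]).
#' @param cfg A [buffer_config()].
#' @param targets Targets to present.
#' @param repeats Presentations per target.
#' @param seed Session seed (target order, per-trial spike noise).
#' @return A list of class `mu_session`: `trials` (list of `mu_trial`),
#'   `info` (tibble: trial, target, outcome, hit buffers), `config`.
#' @export
run_session <- function(pair, policy, ref_rates, gains = c(1, 1),
                        cfg = buffer_config(),
                        targets = c("TI", "TII", "TIII"), repeats = 10,
                        seed = NULL) {
  order <- local_rng(seed, sample(rep(targets, repeats)))
  seeds <- local_rng(seed, sample.int(2^30, length(order)))
  trials <- vector("list", length(order))
  for (i in seq_along(order)) {
    trials[[i]] <- run_closed_loop_trial(
      pair, policy, order[i], ref_rates, gains, cfg, seeds[i])
  }
  info <- purrr::imap_dfr(trials, function(tr, i) {
    tibble(trial = i, target = tr$target, outcome = tr$outcome,
           target_hit_buffer = tr$target_hit_buffer,
           angle_hit_buffer = tr$angle_hit_buffer)
  })
  structure(list(trials = trials, info = info, config = cfg, seed = seed),
            class = "mu_session")
}

#' Simulate one closed-loop trial
#'
#' Drives the pair with `policy`, builds the cursor stream and runs the
#' trial rules. The leading rest segment of the drive (before target onset)
#' is checked for silence and trimmed.
#'
#' @inheritParams run_session
#' @param target Target id for this trial.
#' @param trial_seed Seed for the spike simulation.
#' @return A `mu_trial` with the pair spike trains (trial clock) attached
#'   as `$spikes`.
#' @export
run_closed_loop_trial <- function(pair, policy, target, ref_rates,
                                  gains = c(1, 1), cfg = buffer_config(),
                                  trial_seed = NULL) {
  drive <- policy(target, pair, trial_seed)
  sp <- simulate_spikes(pair, drive, seed = trial_seed)
  horizon <- max(drive$time_s)
  r1 <- buffer_rates(spike_times(sp, pair$unit_id[1]), cfg, horizon)
  r2 <- buffer_rates(spike_times(sp, pair$unit_id[2]), cfg, horizon)
  rates <- bind_rate_pair(r1, r2)

  rest_buffers <- as.integer(floor(cfg$rest_s / cfg$buffer_s))
  if (rest_buffers > 0) {
    lead <- seq_len(min(rest_buffers, nrow(rates)))
    if (any(rates$rate1[lead] > 0 | rates$rate2[lead] > 0))
      warn("discharges during the inter-trial rest segment.")
  }
  stream <- cursor_positions(rates, ref_rates, gains, cfg, init = "zero")
  onset <- rest_buffers + 1L
  stream <- stream[onset:nrow(stream), ]
  stream$buffer <- seq_len(nrow(stream))
  stream$t <- stream$buffer * cfg$buffer_s
  trial <- run_trial(stream, target, cfg)
  # spike times on the trial clock (0 = target onset)
  offset_s <- (onset - 1L) * cfg$buffer_s
  trial$spikes <- dplyr::mutate(sp, time_s = .data$time_s - offset_s)
  attr(trial$spikes, "activation") <- NULL
  trial
}
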