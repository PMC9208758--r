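#' Trapezoidal ramp drive profile
#'
#' Builds the standard force-ramp drive: a linear rise from zero at `slope`,
#' a plateau, and a symmetric linear decline back to zero. The default is the
#' ramp protocol used for threshold estimation: 1 %MVC/s to a 10 %MVC plateau
#' held 10 s, i.e. a 30 s trapezoid.
#'
#' @param slope Ramp slope, %MVC per second (> 0).
#' @param plateau_level Plateau level, %MVC (> 0).
#' @param plateau_dur Plateau duration, seconds.
#' @param fs Sampling rate, Hz (> 0).
#' @param tail_s Optional trailing zero-drive segment, seconds (default 0);
#'   useful so post-ramp silence can elapse inside the analysis horizon.
#' @return A tibble of class `mu_trace` with columns `time_s`, `value` and an
#'   `fs` attribute.
#' @examples
#' ramp <- ramp_drive(1, 10, 10, fs = 256)
#' max(ramp$value)
#' @export
ramp_drive <- function(slope = 1, plateau_level = 10, plateau_dur = 10,
                       fs = 2048, tail_s = 0) {
  stopifnot_scalar_num(slope, "slope", positive = TRUE)
  stopifnot_scalar_num(plateau_level, "plateau_level", positive = TRUE)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (plateau_dur < 0 || tail_s < 0)
    abort("`plateau_dur` and `tail_s` must be >= 0.")
  rise <- plateau_level / slope
  dur <- 2 * rise + plateau_dur + tail_s
  t <- seq(0, dur, by = 1 / fs)
  v <- ifelse(t <= rise, slope * t,
       ifelse(t <= rise + plateau_dur, plateau_level,
       ifelse(t <= 2 * rise + plateau_dur,
              plateau_level - slope * (t - rise - plateau_dur), 0)))
  new_mu_trace(t, pmax(v, 0), fs)
}

new_mu_trace <- function(time_s, value, fs) {
  if (any(diff(time_s) <= 0)) abort("trace times must be strictly increasing.")
  if (any(!is.finite(value))) abort("trace values must be finite.")
  out <- tibble(time_s = time_s, value = value)
  attr(out, "fs") <- fs
  class(out) <- unique(c("mu_trace", class(out)))
  out
}

#' Sampling rate of a trace
#' @param x A `mu_trace`.
#' @return Sampling rate in Hz.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- 1 / median(diff(x$time_s))
  fs
}

#' Three-stage drive policy for reaching the higher-threshold-unit target
#'
#' Builds the piecewise-linear drive implementing the three-stage strategy
#' for activating the higher-threshold unit (MU2) alone: stage 1 rises above
#' both recruitment thresholds to recruit the pair in order; stage 2 lowers
#' the drive into the hysteresis gap so MU1 falls silent while MU2 keeps
#' firing; stage 3 raises the drive slightly (staying below MU1's
#' recruitment threshold) to modulate MU2's rate into the target. The
#' strategy requires reversed hysteresis for MU1 relative to MU2:
#' `theta_off` of MU1 strictly above `max(theta_off(MU2), 0)`. When that gap
#' is empty the profile is still produced (stage 2 just above MU2's
#' de-recruitment level) but flagged infeasible.
#'
#' @param pair A `mu_pool` with exactly 2 rows ordered by `theta_on`
#'   ascending (MU1 first).
#' @param overshoot Stage-1 overshoot above MU2's recruitment threshold, %MVC.
#' @param dwell Hold duration of each stage, seconds.
#' @param fs Sampling rate, Hz.
#' @param transition_slope Slope of the linear transitions, %MVC/s.
#' @param rest_s Leading and trailing zero-drive rest, seconds.
#' @return A `mu_trace` with attributes `stages` (tibble of stage levels and
#'   hold intervals) and `infeasible` (logical).
#' @examples
#' pair <- pool_from_params(theta_on = c(3, 4), theta_off = c(2.5, 1.5))
#' drv <- three_stage_drive(pair, fs = 128)
#' attr(drv, "stages")
#' @export
three_stage_drive <- function(pair, overshoot = 1, dwell = 5, fs = 2048,
                              transition_slope = 1, rest_s = 2) {
  if (nrow(pair) != 2L) abort("`pair` must contain exactly 2 units.")
  if (pair$theta_on[1] > pair$theta_on[2])
    abort("`pair` must be ordered by ascending `theta_on` (MU1 first).")
  th_on1 <- pair$theta_on[1]; th_on2 <- pair$theta_on[2]
  th_off1 <- pair$theta_off[1]; th_off2 <- pair$theta_off[2]

  # stage-2 level must de-recruit MU1 (< theta_off1) without re-recruiting it
  # (< theta_on1) while keeping MU2 firing (> theta_off2)
  floor2 <- max(th_off2, 0)
  ceil2 <- min(th_off1, th_on1)
  infeasible <- ceil2 <= floor2
  l1 <- th_on2 + overshoot
  if (!infeasible) {
    l2 <- floor2 + 0.25 * (ceil2 - floor2)
    l3 <- l2 + 0.5 * (th_on1 - l2)
  } else {
    l2 <- floor2 + 0.1
    l3 <- l2 + 0.3
  }

  # piecewise-linear node list: (duration of segment, end level)
  lev <- c(0, l1, l1, l2, l2, l3, l3, 0)
  durs <- c(l1 / transition_slope, dwell,
            abs(l1 - l2) / transition_slope, dwell,
            abs(l3 - l2) / transition_slope, dwell,
            l3 / transition_slope)
  node_t <- rest_s + c(0, cumsum(durs))
  total <- node_t[length(node_t)] + rest_s
  t <- seq(0, total, by = 1 / fs)
  v <- approx(c(0, node_t, total), c(0, lev, 0), xout = t, rule = 2)$y

  holds <- tibble(
    stage = 1:3,
    level = c(l1, l2, l3),
    t_start = node_t[c(2, 4, 6)],
    t_end = node_t[c(3, 5, 7)]
  )
  out <- new_mu_trace(t, pmax(v, 0), fs)
  attr(out, "stages") <- holds
  attr(out, "infeasible") <- infeasible
  out
}

#' Random piecewise-linear drive policy
#'
#' Draws a random hold-and-transition drive profile bounded by `max_level`,
#' used to probe the task engine with arbitrary force strategies.
#'
#' @param max_level Upper bound of drive levels, %MVC.
#' @param n_segments Number of random hold levels.
#' @param dwell Hold duration per level, seconds.
#' @param fs Sampling rate, Hz.
#' @param transition_slope Transition slope, %MVC/s.
#' @param rest_s Leading/trailing rest, seconds.
#' @param seed Integer seed.
#' @return A `mu_trace`.
#' @export
random_drive <- function(max_level = 10, n_segments = 4, dwell = 3, fs = 2048,
                         transition_slope = 2, rest_s = 2, seed = NULL) {
  local_rng(seed, {
    lev <- runif(n_segments, 0, max_level)
    lev_full <- c(0, rep(lev, each = 2), 0)
    node_durs <- numeric(0)
    prev <- 0
    for (l in lev) {
      node_durs <- c(node_durs, abs(l - prev) / transition_slope, dwell)
      prev <- l
    }
    node_durs <- c(node_durs, prev / transition_slope)
    node_t <- rest_s + c(0, cumsum(node_durs))
    total <- node_t[length(node_t)] + rest_s
    t <- seq(0, total, by = 1 / fs)
    v <- approx(c(0, node_t, total), c(0, lev_full, 0), xout = t, rule = 2)$y
    new_mu_trace(t, pmax(v, 0), fs)
  })
}
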