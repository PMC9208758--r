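#' Raw trial performance
#'
#' Sums, over the `N` buffers from target onset to trial end,
#' `(d(n)/dmax)^2 + (phi(n)/phi_max)^2`, where `d(n)` is the Euclidean
#' distance from cursor to target centre and `phi(n)` the absolute angle
#' (degrees) between cursor and target-centre vectors; a cursor at the
#' origin contributes `phi = phi_max`. Lower is better. Because the
#' typeset definition is ambiguous about a per-buffer square root, a
#' root-sum-square variant is available.
#'
#' @param trial A `mu_trial` (or a `mu_cursor` stream).
#' @param geom A [target_geometry()]; defaults to the trial's own.
#' @param variant `"sum_of_squares"` (default, the printed form) or
#'   `"rss"` (per-buffer Euclidean norm).
#' @return Raw performance (dimensionless, >= 0).
#' @export
performance_raw <- function(trial, geom = NULL,
                            variant = c("sum_of_squares", "rss")) {
  variant <- arg_match(variant)
  stream <- if (inherits(trial, "mu_trial")) trial$stream else trial
  if (is.null(geom)) {
    if (!inherits(trial, "mu_trial")) abort("`geom` is required for a bare stream.")
    geom <- trial$geometry
  }
  if (!nrow(stream)) abort("trial has no buffers.")
  d <- sqrt((stream$x - geom$center[1])^2 + (stream$y - geom$center[2])^2)
  phi <- cursor_angle(stream$x, stream$y, geom)
  terms <- (d / geom$dmax)^2 + (phi / geom$phi_max)^2
  if (variant == "rss") sum(sqrt(terms)) else sum(terms)
}

#' Best and worst performance bounds for a target
#'
#' The worst value is the performance of a cursor held at the origin for
#' the full timeout (`timeout_buffers * ((|center|/dmax)^2 + 1)`). The best
#' value is the performance of the idealised trajectory: constant discharge
#' rates matching the target's required activation, fed from rest through
#' the cursor pipeline until the trial rules report the hit.
#'
#' @param target Target id or [target_geometry()].
#' @param cfg A [buffer_config()].
#' @param ref_rate Reference rate (pps) used for the idealised simulation.
#' @param variant Metric variant, see [performance_raw()].
#' @return Named list `best_raw`, `worst_raw`, plus the ideal `trial`.
#' @export
performance_bounds <- function(target, cfg = buffer_config(), ref_rate = 10,
                               variant = c("sum_of_squares", "rss")) {
  variant <- arg_match(variant)
  geom <- if (inherits(target, "mu_geometry")) target else target_geometry(target)
  cn <- sqrt(sum(geom$center^2))
  worst_term <- (cn / geom$dmax)^2 + 1
  worst_raw <- cfg$timeout_buffers *
    (if (variant == "rss") sqrt(worst_term) else worst_term)

  rates <- tibble(
    buffer = seq_len(cfg$timeout_buffers),
    rate1 = geom$center[1] * ref_rate,
    rate2 = geom$center[2] * ref_rate
  )
  stream <- cursor_positions(rates, ref_rates = c(ref_rate, ref_rate),
                             gains = c(1, 1), cfg = cfg, init = "zero")
  trial <- run_trial(stream, geom, cfg)
  if (trial$outcome != "target_hit")
    abort("idealised trajectory failed to hit the target; check the config.")
  best_raw <- performance_raw(trial, geom, variant)
  list(best_raw = best_raw, worst_raw = worst_raw, trial = trial)
}

#' Normalise a raw performance value to [0, 1]
#'
#' `(worst - raw) / (worst - best)`, clipped to `[0, 1]`; 1 is the
#' idealised trajectory, 0 the origin-hold trial.
#'
#' @param raw Raw performance.
#' @param bounds List with `best_raw` and `worst_raw` (see
#'   [performance_bounds()]).
#' @return Normalised performance in `[0, 1]`.
#' @export
performance_normalized <- function(raw, bounds) {
  if (bounds$worst_raw <= bounds$best_raw)
    abort("degenerate bounds: worst_raw must exceed best_raw.")
  pmin(1, pmax(0, (bounds$worst_raw - raw) /
                    (bounds$worst_raw - bounds$best_raw)))
}

#' Nearest miss of an unsuccessful trial
#'
#' The average cursor position over any window of `hold_buffers`
#' consecutive buffers (875 ms) that comes closest to the target centre;
#' ties resolve to the earliest window.
#'
#' @param trial A `mu_trial` without a target hit.
#' @param geom Geometry; defaults to the trial's own.
#' @param cfg A [buffer_config()].
#' @return One-row tibble `x`, `y`, `window_start`, `window_end`,
#'   `distance`; zero rows when the trial is shorter than the hold window.
#' @export
nearest_miss <- function(trial, geom = NULL, cfg = buffer_config()) {
  if (!is.na(trial$target_hit_buffer))
    abort("nearest miss is defined only for trials without a target hit.")
  if (is.null(geom)) geom <- trial$geometry
  stream <- trial$stream
  k <- cfg$hold_buffers
  n <- nrow(stream)
  if (n < k)
    return(tibble(x = double(), y = double(), window_start = integer(),
                  window_end = integer(), distance = double()))
  mx <- trailing_mean(stream$x, k, init = "zero")[k:n]
  my <- trailing_mean(stream$y, k, init = "zero")[k:n]
  dist <- sqrt((mx - geom$center[1])^2 + (my - geom$center[2])^2)
  i <- which.min(dist)  # which.min takes the earliest minimiser
  tibble(x = mx[i], y = my[i], window_start = i, window_end = i + k - 1L,
         distance = dist[i])
}

#' Unintended target and angle hits
#'
#' Counts, for every non-selected target, the maximal excursions of the
#' cursor that stay inside the target disc (and, separately, inside the
#' angle wedge, with the disc counting as inside the wedge) for at least
#' `hold_buffers` consecutive buffers. Re-entries count separately, so
#' per-trial counts can exceed one.
#'
#' @param trial A `mu_trial`.
#' @param cfg A [buffer_config()].
#' @param targets Targets to scan; defaults to all targets other than the
#'   trial's own.
#' @return Tibble `target`, `region` (`"target"`/`"angle"`), `count`.
#' @export
unintended_hits <- function(trial, cfg = buffer_config(), targets = NULL) {
  if (is.null(targets))
    targets <- setdiff(c("TI", "TII", "TIII"), trial$target)
  stream <- trial$stream
  purrr::map_dfr(targets, function(tg) {
    g <- target_geometry(tg)
    lab <- point_region(stream$x, stream$y, g)
    n_target <- count_long_runs(lab == "target", cfg$hold_buffers)
    n_wedge <- count_long_runs(lab %in% c("target", "angle"),
                               cfg$hold_buffers)
    tibble(target = tg,
           region = c("target", "angle"),
           count = c(n_target, n_wedge))
  })
}

count_long_runs <- function(flags, min_len) {
  r <- rle(flags)
  sum(r$values & r$lengths >= min_len)
}

#' Classify a successful attempt as a direct movement
#'
#' A TI attempt is direct when MU2 discharged no spike between target onset
#' and the qualifying (angle or target) hit; a TIII attempt is direct when
#' MU1 discharged none. Other targets, and trials without any qualifying
#' hit, return `NA`.
#'
#' @param trial A `mu_trial` (with spike times on the trial clock in
#'   `$spikes`, as produced by [run_closed_loop_trial()], unless given
#'   explicitly).
#' @param times_mu1,times_mu2 Spike times of MU1/MU2 on the trial clock.
#' @param cfg A [buffer_config()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
classify_direct <- function(trial, times_mu1 = NULL, times_mu2 = NULL,
                            cfg = buffer_config()) {
  if (is.null(times_mu1) || is.null(times_mu2)) {
    if (is.null(trial$spikes)) abort("spike times are required.")
    units <- unique(trial$spikes$unit_id)
    times_mu1 <- spike_times(trial$spikes, units[1])
    times_mu2 <- spike_times(trial$spikes, units[2])
  }
  if (!trial$target %in% c("TI", "TIII")) return(NA)
  hit_b <- suppressWarnings(
    min(trial$target_hit_buffer, trial$angle_hit_buffer, na.rm = TRUE))
  if (!is.finite(hit_b)) return(NA)
  t_end <- hit_b * cfg$buffer_s
  other <- if (trial$target == "TI") times_mu2 else times_mu1
  sum(other >= 0 & other <= t_end) == 0
}

#' Characteristic forces of the three-stage strategy
#'
#' For indirect TIII target hits: `f1` is the mean force in a 100 ms window
#' centred at the maximum force while both units are active (trailing
#' 1 s discharge rate above `rate_thresh` pps); `f2` the same at the
#' minimum force during the MU1-silent/MU2-firing epoch after the
#' both-active epoch; `f3` the mean force over the `hold_buffers` (875 ms)
#' preceding the target hit.
#'
#' @param trial A TIII `mu_trial` with a target hit.
#' @param force A `mu_trace` of force on the trial clock.
#' @param cfg A [buffer_config()].
#' @param rate_thresh Activity criterion on the trailing rate, pps.
#' @param window_ms Force-window length, milliseconds.
#' @return One-row tibble `f1`, `f2`, `f3` (%MVC); fields are `NA` with a
#'   warning when a required epoch is absent (e.g. a direct hit).
#' @export
stage_forces <- function(trial, force, cfg = buffer_config(),
                         rate_thresh = 5, window_ms = 100) {
  out <- tibble(f1 = NA_real_, f2 = NA_real_, f3 = NA_real_)
  if (trial$target != "TIII" || is.na(trial$target_hit_buffer)) {
    warn("stage forces require a TIII target hit.")
    return(out)
  }
  stream <- trial$stream
  both <- stream$rbar1 > rate_thresh & stream$rbar2 > rate_thresh
  if (!any(both)) {
    warn("no both-active epoch (direct hit); stage forces absent.")
    return(out)
  }
  window_force <- function(t) {
    tryCatch(force_at_event(force, t, window_ms), error = function(e) {
      sel <- abs(force$time_s - t) <= window_ms / 2000
      mean(force$value[sel])
    })
  }
  f_at_buffers <- approx(force$time_s, force$value, stream$t, rule = 2)$y
  ib <- which(both)
  t1 <- stream$t[ib[which.max(f_at_buffers[ib])]]
  out$f1 <- window_force(t1)

  solo <- which(stream$rbar1 <= rate_thresh & stream$rbar2 > rate_thresh &
                  stream$buffer > min(ib))
  if (length(solo)) {
    t2 <- stream$t[solo[which.min(f_at_buffers[solo])]]
    out$f2 <- window_force(t2)
  } else {
    warn("no MU1-silent/MU2-firing epoch; f2 absent.")
  }

  t_hit <- trial$target_hit_buffer * cfg$buffer_s
  sel <- force$time_s >= t_hit - cfg$hold_buffers * cfg$buffer_s - 1e-9 &
    force$time_s <= t_hit + 1e-9
  out$f3 <- mean(force$value[sel])
  out
}

#' Within-session learning correlation
#'
#' Spearman rank correlation between trial index and normalised
#' performance: positive values mean improvement over the session.
#'
#' @param performances Ordered per-trial normalised performance values
#'   (>= 3).
#' @return Correlation coefficient; 0 with a warning when performances are
#'   constant.
#' @export
learning_correlation <- function(performances) {
  if (length(performances) < 3)
    abort("at least 3 trials are required.")
  if (sd(performances) == 0) {
    warn("constant performances; correlation undefined, returning 0.")
    return(0)
  }
  cor(seq_along(performances), performances, method = "spearman")
}
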