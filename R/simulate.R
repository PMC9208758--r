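# Activation state machine for one unit over a sampled drive.
# A unit recruits when the drive reaches theta_on and de-recruits when the
# drive falls below theta_off *on the way down*, i.e. when it is both below
# theta_off and below its running maximum since recruitment. For
# theta_off <= theta_on this is exactly the plain two-threshold machine.
# For theta_off > theta_on (de-recruitment above the recruitment level) two
# refinements keep the machine well defined: the running-max condition stops
# the unit from de-recruiting while the drive is still rising through the
# band [theta_on, theta_off), and after de-recruitment the unit is re-armed
# only once the drive has dropped below theta_on, so it does not chatter
# back on inside the band it just de-recruited in. An unreachably high
# theta_off is effectively capped at the peak drive attained.
# Returns a tibble of activation episodes (t_on, t_off).
activation_episodes <- function(unit, drive) {
  t <- drive$time_s
  v <- drive$value
  n <- length(t)
  active <- FALSE
  armed <- TRUE
  run_max <- -Inf
  t_on <- numeric(0)
  t_off <- numeric(0)
  for (i in seq_len(n)) {
    if (!active) {
      if (!armed && v[i] < unit$theta_on) armed <- TRUE
      if (armed && v[i] >= unit$theta_on) {
        active <- TRUE
        run_max <- v[i]
        t_on <- c(t_on, t[i])
      }
    } else {
      if (v[i] < unit$theta_off && v[i] < run_max) {
        active <- FALSE
        armed <- v[i] < unit$theta_on
        t_off <- c(t_off, t[i])
      } else {
        run_max <- max(run_max, v[i])
      }
    }
  }
  if (active) t_off <- c(t_off, t[n])
  tibble(t_on = t_on, t_off = t_off)
}

# Summed instantaneous pool discharge rate (pps) on the drive grid, using
# the deterministic activation machine; drives the EMG amplitude model.
activity_trace <- function(pool, drive) {
  total <- numeric(nrow(drive))
  for (k in seq_len(nrow(pool))) {
    unit <- pool[k, ]
    ep <- activation_episodes(unit, drive)
    if (!nrow(ep)) next
    act <- rep(FALSE, nrow(drive))
    for (j in seq_len(nrow(ep)))
      act <- act | (drive$time_s >= ep$t_on[j] & drive$time_s <= ep$t_off[j])
    total[act] <- total[act] + unit_rate(unit, drive$value[act])
  }
  total
}

#' Simulate motor-unit spike trains under a common drive
#'
#' Runs the per-unit recruitment state machine over the drive and draws
#' spikes as a renewal process while each unit is active. The instantaneous
#' rate is `min(r_sat, r_min + rate_gain * (drive - theta_on))`, floored at
#' `r_min`; inter-spike intervals are the reciprocal rate perturbed by a
#' Gaussian factor with coefficient of variation `isi_cov`, truncated below
#' at 20% of the mean interval. Units recruit in ascending `theta_on` order
#' on any rising drive (size principle) and de-recruit when the drive falls
#' below their own `theta_off`.
#'
#' @param pool A `mu_pool`.
#' @param drive A `mu_trace` covering at least 1 s.
#' @param seed Integer seed; identical pool + drive + seed reproduce the
#'   trains exactly.
#' @return A tibble of class `mu_spikes` with columns `unit_id`, `time_s`,
#'   plus an `activation` attribute: a tibble of per-unit activation episodes
#'   (`unit_id`, `t_on`, `t_off`). Retrieve it with [activation_intervals()].
#' @examples
#' pool <- pool_from_params(theta_on = c(2, 4), theta_off = c(1, 2))
#' sp <- simulate_spikes(pool, ramp_drive(1, 10, 10, fs = 128), seed = 1)
#' head(sp)
#' @export
simulate_spikes <- function(pool, drive, seed = NULL) {
  if (!nrow(pool)) abort("`pool` is empty.")
  if (diff(range(drive$time_s)) < 1)
    abort("`drive` must cover at least 1 s.")
  local_rng(seed, {
    all_units <- vector("list", nrow(pool))
    all_eps <- vector("list", nrow(pool))
    for (k in seq_len(nrow(pool))) {
      unit <- pool[k, ]
      ep <- activation_episodes(unit, drive)
      all_eps[[k]] <- if (nrow(ep)) bind_cols(unit_id = unit$unit_id, ep) else NULL
      spikes <- numeric(0)
      for (j in seq_len(nrow(ep))) {
        t_cur <- ep$t_on[j]
        t_end <- ep$t_off[j] + 1e-9
        while (t_cur <= t_end) {
          spikes <- c(spikes, t_cur)
          d <- approx(drive$time_s, drive$value, t_cur, rule = 2)$y
          rate <- unit_rate(unit, d)
          fac <- if (unit$isi_cov > 0) max(0.2, rnorm(1, 1, unit$isi_cov)) else 1
          t_cur <- t_cur + fac / rate
        }
      }
      all_units[[k]] <- tibble(unit_id = unit$unit_id, time_s = spikes)
    }
    out <- bind_rows(all_units)
    attr(out, "activation") <- bind_rows(all_eps)
    class(out) <- unique(c("mu_spikes", class(out)))
    out
  })
}

#' Per-unit activation episodes of a simulated spike set
#' @param x A `mu_spikes` object from [simulate_spikes()].
#' @return Tibble with `unit_id`, `t_on`, `t_off` per activation episode.
#' @export
activation_intervals <- function(x) {
  act <- attr(x, "activation")
  if (is.null(act)) abort("`x` carries no activation attribute.")
  act
}

#' Extract one unit's spike times
#' @param spikes A `mu_spikes` tibble (or any tibble with `unit_id`, `time_s`).
#' @param unit Unit identifier.
#' @return Numeric vector of discharge times, seconds.
#' @export
spike_times <- function(spikes, unit) {
  sort(spikes$time_s[spikes$unit_id == unit])
}

#' Simulate a measured force trace from a drive
#'
#' The measured dorsiflexion force is modelled as the common drive plus
#' zero-mean low-pass (< 5 Hz) noise; with `noise_sd = 0` the force equals
#' the drive exactly.
#'
#' @param drive A `mu_trace`.
#' @param noise_sd Standard deviation of the additive noise, %MVC.
#' @param seed Integer seed.
#' @return A `mu_trace` on the same time grid.
#' @export
simulate_force <- function(drive, noise_sd = 0.1, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  v <- drive$value
  if (noise_sd > 0) {
    fs <- trace_fs(drive)
    local_rng(seed, {
      eps <- rnorm(length(v))
      bf <- signal::butter(4, min(5 / (fs / 2), 0.99), type = "low")
      eps <- signal::filtfilt(bf, eps)
      eps <- eps - mean(eps)
      v <- v + eps * (noise_sd / sd(eps))
    })
  }
  new_mu_trace(drive$time_s, v, trace_fs(drive))
}

#' Simulate multichannel global-EMG-like signals
#'
#' Each channel is a zero-mean white carrier amplitude-modulated by the
#' summed discharge rate of the active pool (deterministic activation, no
#' spike noise) plus additive sensor noise. The rectified, low-pass-filtered
#' envelope of such a channel grows monotonically with summed pool activity,
#' which is the property the envelope analyses consume.
#'
#' @param pool A `mu_pool`.
#' @param drive A `mu_trace`.
#' @param channels Character vector of channel (muscle) labels.
#' @param noise_sd Additive noise standard deviation (signal units).
#' @param seed Integer seed.
#' @return A tibble of class `mu_emg`: `time_s` plus one column per channel;
#'   attributes `fs` and `channel_gains`.
#' @export
simulate_global_emg <- function(pool, drive,
                                channels = c("TA", "FL", "GL", "GM"),
                                noise_sd = 0.01, seed = NULL) {
  a <- activity_trace(pool, drive)
  n <- length(a)
  local_rng(seed, {
    gains <- setNames(runif(length(channels), 0.5, 1.5), channels)
    out <- tibble(time_s = drive$time_s)
    for (ch in channels) {
      carrier <- rnorm(n)
      noise <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
      out[[ch]] <- gains[[ch]] * a * carrier + noise
    }
    attr(out, "fs") <- trace_fs(drive)
    attr(out, "channel_gains") <- gains
    class(out) <- unique(c("mu_emg", class(out)))
    out
  })
}

#' Corrupt a spike train into a simulated second decomposition source
#'
#' Emulates an imperfect second decomposition of the same MU activity (e.g.
#' an intramuscular recording): each discharge is deleted independently with
#' probability `p_miss`, survivors are jittered by zero-mean Gaussian noise,
#' and spurious discharges are inserted uniformly over the train's span at a
#' rate of `p_extra` times the original count.
#'
#' @param times Numeric vector of discharge times, seconds (sorted).
#' @param jitter_sd_ms Jitter standard deviation, milliseconds.
#' @param p_miss Per-discharge deletion probability in `[0, 1)`.
#' @param p_extra Expected spurious discharges as a fraction of the original
#'   count (>= 0).
#' @param seed Integer seed.
#' @return Sorted numeric vector of corrupted discharge times.
#' @export
corrupt_spike_train <- function(times, jitter_sd_ms = 0.3, p_miss = 0.05,
                                p_extra = 0.02, seed = NULL) {
  if (p_miss < 0 || p_miss >= 1) abort("`p_miss` must be in [0, 1).")
  if (p_extra < 0) abort("`p_extra` must be >= 0.")
  times <- sort(as.numeric(times))
  n <- length(times)
  if (!n) return(numeric(0))
  local_rng(seed, {
    keep <- runif(n) >= p_miss
    out <- times[keep]
    if (jitter_sd_ms > 0 && length(out))
      out <- out + rnorm(length(out), sd = jitter_sd_ms / 1000)
    n_extra <- stats::rpois(1, p_extra * n)
    if (n_extra > 0)
      out <- c(out, runif(n_extra, min(times), max(times)))
    sort(out)
  })
}
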