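#' Detect motor-unit recruitment onset
#'
#' Onset is the time a unit starts discharging at `rate_thresh` pps or
#' above, read instantaneously: the first spike that begins a run of at
#' least two spikes whose inter-spike interval is `<= 1/rate_thresh`.
#'
#' @param times Numeric vector of discharge times, seconds, sorted.
#' @param rate_thresh Onset rate criterion, pps (default 5, i.e. ISI
#'   <= 200 ms).
#' @return Onset time in seconds, or `NA` (with a warning when fewer than
#'   two spikes are available).
#' @examples
#' detect_onset(c(1.0, 1.4, 1.62, 1.80, 1.95))  # 1.62
#' @export
detect_onset <- function(times, rate_thresh = 5) {
  times <- sort(as.numeric(times))
  if (length(times) < 2) {
    warn("fewer than 2 spikes; onset undefined.")
    return(NA_real_)
  }
  isi <- diff(times)
  i <- which(isi <= 1 / rate_thresh + 1e-12)[1]
  if (is.na(i)) return(NA_real_)
  times[i]
}

#' Detect motor-unit de-recruitment offset
#'
#' Offset is the last discharge before the unit turns silent for at least
#' `silence` seconds. The gap to `horizon_end` counts as silence, and when
#' several silent episodes exist the offset of the final activation episode
#' is returned.
#'
#' @param times Discharge times, seconds, sorted.
#' @param silence Minimum silent gap, seconds (default 1.5).
#' @param horizon_end End of the analysis interval, seconds.
#' @return Offset time in seconds, or `NA` when no spike qualifies.
#' @examples
#' detect_offset(c(5.0, 5.1, 7.2), horizon_end = 10)  # 7.2
#' @export
detect_offset <- function(times, silence = 1.5, horizon_end) {
  times <- sort(as.numeric(times))
  if (!length(times)) return(NA_real_)
  gaps <- c(diff(times), horizon_end - times[length(times)])
  ok <- which(gaps >= silence - 1e-12)
  if (!length(ok)) return(NA_real_)
  times[max(ok)]
}

#' Mean force in a window centred on an event
#'
#' Averages the force samples inside the closed window
#' `[t - window_ms/2, t + window_ms/2]`; the 100 ms default is the window
#' used to read the force at recruitment and de-recruitment events.
#'
#' @param force A `mu_trace` of force values (%MVC).
#' @param t Event time, seconds.
#' @param window_ms Window length, milliseconds.
#' @return Mean force, %MVC.
#' @export
force_at_event <- function(force, t, window_ms = 100) {
  half <- window_ms / 2000
  lo <- t - half
  hi <- t + half
  rng <- range(force$time_s)
  if (lo < rng[1] - 1e-9 || hi > rng[2] + 1e-9)
    abort(sprintf(
      "window [%.4f, %.4f] s overhangs the trace [%.4f, %.4f] s.",
      lo, hi, rng[1], rng[2]))
  sel <- force$time_s >= lo - 1e-9 & force$time_s <= hi + 1e-9
  mean(force$value[sel])
}

#' Average discharge rate over the plateau
#'
#' The reference discharge rate used to normalise cursor feedback: spike
#' count over the plateau interval divided by its duration.
#'
#' @param times Discharge times, seconds.
#' @param plateau Length-2 numeric, plateau interval `[t1, t2)` in seconds
#'   (at least 1 s long).
#' @return Rate in pps; 0 with a warning when the unit is silent on the
#'   plateau (unusable as a feedback source).
#' @export
estimate_reference_rate <- function(times, plateau) {
  if (length(plateau) != 2L || diff(plateau) < 1)
    abort("`plateau` must be an interval of at least 1 s.")
  n <- sum(times >= plateau[1] & times < plateau[2])
  if (n == 0) warn("no discharges on the plateau; reference rate is 0.")
  n / diff(plateau)
}

#' Estimate thresholds and rank a pool from one ramp trial
#'
#' For every unit: detects recruitment onset (5 pps rule) and de-recruitment
#' offset (1.5 s silence rule), reads the force in 100 ms windows centred on
#' both events, optionally estimates the plateau reference rate, and ranks
#' units by ascending recruitment force (ties broken by earlier onset, then
#' unit id). Units without a detectable onset are excluded with a warning
#' and listed in the `excluded` attribute.
#'
#' @param spikes A `mu_spikes` tibble (`unit_id`, `time_s`).
#' @param force A `mu_trace` of force, %MVC.
#' @param rate_thresh Onset rate criterion, pps.
#' @param silence Offset silence criterion, seconds.
#' @param window_ms Force-window length, milliseconds.
#' @param plateau Optional plateau interval for the reference rate.
#' @return A tibble of class `mu_thresholds`: `unit_id`, `rank`, `t_on`,
#'   `f_on`, `t_off`, `f_off`, `ref_rate`.
#' @export
rank_pool <- function(spikes, force, rate_thresh = 5, silence = 1.5,
                      window_ms = 100, plateau = NULL) {
  units <- unique(spikes$unit_id)
  horizon <- max(force$time_s)
  rows <- purrr::map(units, function(u) {
    tt <- spike_times(spikes, u)
    t_on <- suppressWarnings(detect_onset(tt, rate_thresh))
    if (is.na(t_on)) return(NULL)
    f_on <- tryCatch(force_at_event(force, t_on, window_ms),
                     error = function(e) NA_real_)
    if (is.na(f_on)) return(NULL)
    t_off <- detect_offset(tt, silence, horizon)
    f_off <- if (!is.na(t_off))
      tryCatch(force_at_event(force, t_off, window_ms),
               error = function(e) NA_real_) else NA_real_
    ref <- if (!is.null(plateau))
      suppressWarnings(estimate_reference_rate(tt, plateau)) else NA_real_
    tibble(unit_id = u, t_on = t_on, f_on = f_on,
           t_off = t_off, f_off = f_off, ref_rate = ref)
  })
  keep <- !purrr::map_lgl(rows, is.null)
  excluded <- units[!keep]
  if (length(excluded))
    warn(paste0("units without detectable onset excluded: ",
                paste(excluded, collapse = ", ")))
  out <- bind_rows(rows[keep])
  if (!nrow(out)) abort("no unit has a detectable onset.")
  out <- out %>%
    arrange(.data$f_on, .data$t_on, .data$unit_id) %>%
    mutate(rank = row_number()) %>%
    select("unit_id", "rank", "t_on", "f_on", "t_off", "f_off", "ref_rate")
  attr(out, "excluded") <- excluded
  class(out) <- unique(c("mu_thresholds", class(out)))
  out
}

#' Ramp tracking error and first-tracked-ramp selection
#'
#' Only the first successfully tracked ramp feeds threshold estimation.
#' "Successfully tracked" is operationalised as a bound on the RMS error
#' between the measured force and the target ramp profile, in %MVC (the
#' emulated protocol states no criterion, so the bound is configurable).
#'
#' @param force A `mu_trace` of measured force.
#' @param target A `mu_trace` of the target ramp profile on the same grid.
#' @return RMS tracking error, %MVC.
#' @export
ramp_rms_error <- function(force, target) {
  if (nrow(force) != nrow(target))
    abort("`force` and `target` must share one time grid.")
  sqrt(mean((force$value - target$value)^2))
}

#' @rdname ramp_rms_error
#' @param forces List of measured force traces, one per ramp attempt.
#' @param max_rms Acceptance bound on the RMS error, %MVC.
#' @return `first_tracked_ramp()`: the index of the first ramp whose RMS
#'   error is within `max_rms`, or `NA` (with a warning) when none
#'   qualifies.
#' @export
first_tracked_ramp <- function(forces, target, max_rms = 1) {
  for (i in seq_along(forces)) {
    if (ramp_rms_error(forces[[i]], target) <= max_rms) return(i)
  }
  warn("no ramp tracked within the RMS bound.")
  NA_integer_
}

#' Select the condition I/II/III motor-unit pairs
#'
#' Splits the ranked pool into the first- and last-recruited halves (an odd
#' unit goes to the first half), picks within each half one adjacent-rank
#' pair with probability weighted towards the smallest recruitment-force
#' difference, and forms the three task conditions: condition I is the
#' low-threshold pair, condition II the high-threshold pair, and condition
#' III pools the lower-threshold unit of the low pair with the
#' higher-threshold unit of the high pair. Within every pair MU1 is the
#' lower-threshold unit.
#'
#' @param thresholds A ranked `mu_thresholds` tibble with at least 4 units.
#' @param seed Integer seed for the weighted pair choice.
#' @return Tibble with one row per condition (`condition`, `unit_1`,
#'   `unit_2`, `f_on_1`, `f_on_2`).
#' @export
select_pairs <- function(thresholds, seed = NULL) {
  k <- nrow(thresholds)
  if (k < 4) abort("pair selection requires at least 4 ranked units.")
  th <- arrange(thresholds, .data$rank)
  n_low <- ceiling(k / 2)
  halves <- list(low = th[seq_len(n_low), ],
                 high = th[(n_low + 1):k, ])
  pick <- local_rng(seed, {
    purrr::map(halves, function(h) {
      idx <- seq_len(nrow(h) - 1)
      dfon <- abs(h$f_on[idx + 1] - h$f_on[idx])
      w <- 1 / (dfon + 0.05)
      i <- if (length(idx) == 1) 1L else sample(idx, 1, prob = w)
      h[c(i, i + 1), ]
    })
  })
  low <- pick$low; high <- pick$high
  tibble(
    condition = c("I", "II", "III"),
    unit_1 = c(low$unit_id[1], high$unit_id[1], low$unit_id[1]),
    unit_2 = c(low$unit_id[2], high$unit_id[2], high$unit_id[2]),
    f_on_1 = c(low$f_on[1], high$f_on[1], low$f_on[1]),
    f_on_2 = c(low$f_on[2], high$f_on[2], high$f_on[2])
  )
}

#' Global EMG envelope
#'
#' Rectifies each channel and low-pass filters it at `cutoff` Hz with a
#' zero-phase (forward-backward) Butterworth filter of the given order.
#' Optional bipolar derivations are formed before rectification. Zero-phase
#' filtering is used so 100 ms window reads are not shifted by group delay;
#' this deliberately differs from a causal online implementation.
#'
#' @param emg A `mu_emg` tibble (`time_s` plus channel columns) or any
#'   tibble laid out that way with an `fs` attribute.
#' @param fs Sampling rate, Hz; defaults to the `fs` attribute.
#' @param cutoff Low-pass cutoff, Hz (default 10).
#' @param order Butterworth order (default 4).
#' @param pairs Optional list of length-2 character vectors naming channel
#'   pairs for bipolar derivation (`A - B`).
#' @return Tibble of envelope traces with the same layout, class
#'   `mu_envelope`.
#' @export
emg_envelope <- function(emg, fs = NULL, cutoff = 10, order = 4,
                         pairs = NULL) {
  if (is.null(fs)) fs <- attr(emg, "fs")
  if (is.null(fs)) abort("`fs` is required (none attached to `emg`).")
  if (fs <= 2 * cutoff)
    abort(sprintf("fs (%g Hz) must exceed twice the cutoff (%g Hz).",
                  fs, cutoff))
  chans <- setdiff(names(emg), "time_s")
  src <- as_tibble(emg[chans])
  if (!is.null(pairs)) {
    src <- purrr::map_dfc(pairs, function(p) {
      tibble::as_tibble_col(emg[[p[1]]] - emg[[p[2]]],
                            column_name = paste(p, collapse = "-"))
    })
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- tibble(time_s = emg$time_s)
  for (ch in names(src)) {
    rect <- abs(src[[ch]])
    out[[ch]] <- if (all(rect == 0)) rect else signal::filtfilt(bf, rect)
  }
  attr(out, "fs") <- fs
  class(out) <- unique(c("mu_envelope", class(out)))
  out
}

#' Pre/post change of per-unit measurements
#'
#' Percent change `100 * (post - pre) / pre` for envelope-type values, or
#' absolute difference (%MVC) for force-type values, per unit and on
#' average. Units with a zero pre value are excluded from percent changes
#' with a warning.
#'
#' @param pre,post Matched numeric vectors of per-unit measurements.
#' @param unit_id Optional unit labels.
#' @param type `"percent"` (envelopes) or `"absolute"` (force).
#' @return Tibble (`unit_id`, `pre`, `post`, `change`) with a `mean_change`
#'   attribute.
#' @export
pre_post_change <- function(pre, post, unit_id = NULL,
                            type = c("percent", "absolute")) {
  type <- arg_match(type)
  if (length(pre) != length(post))
    abort("`pre` and `post` must be matched (equal length).")
  if (is.null(unit_id)) unit_id <- paste0("MU", seq_along(pre))
  out <- tibble(unit_id = unit_id, pre = pre, post = post)
  if (type == "percent") {
    bad <- out$pre == 0
    if (any(bad)) {
      warn(paste0("zero pre value; excluded: ",
                  paste(out$unit_id[bad], collapse = ", ")))
      out <- out[!bad, ]
    }
    out$change <- 100 * (out$post - out$pre) / out$pre
  } else {
    out$change <- out$post - out$pre
  }
  attr(out, "mean_change") <- mean(out$change)
  out
}
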