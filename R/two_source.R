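#' Match discharges between two decompositions of one unit
#'
#' Greedy chronological one-to-one matching: both trains are walked in
#' time order and the nearest remaining candidates within `tol_ms` are
#' paired; no spike is reused. On physiological trains, whose inter-spike
#' intervals far exceed twice the tolerance, this equals the optimal
#' bipartite matching.
#'
#' @param a,b Sorted discharge times, seconds.
#' @param tol_ms Maximum |time_a - time_b| for a match, milliseconds
#'   (default 1).
#' @return A list of class `mu_matching`: `pairs` (tibble `time_a`,
#'   `time_b`), `unmatched_a`, `unmatched_b`, `tol_ms`.
#' @examples
#' m <- match_discharges(c(0.1, 0.2, 0.3), c(0.1005, 0.2, 0.45))
#' m$pairs
#' @export
match_discharges <- function(a, b, tol_ms = 1) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  tol <- tol_ms / 1000
  na <- length(a); nb <- length(b)
  pa <- integer(0); pb <- integer(0)
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    if (abs(d) <= tol + 1e-12) {
      # prefer the strictly closer of the two next candidates
      if (j < nb && abs(a[i] - b[j + 1]) < abs(d) &&
          !(i < na && abs(a[i + 1] - b[j]) <= tol + 1e-12)) {
        j <- j + 1L
        next
      }
      pa <- c(pa, i); pb <- c(pb, j)
      i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  structure(list(
    pairs = tibble(time_a = a[pa], time_b = b[pb]),
    unmatched_a = a[setdiff(seq_len(na), pa)],
    unmatched_b = b[setdiff(seq_len(nb), pb)],
    tol_ms = tol_ms
  ), class = "mu_matching")
}

#' Rate of agreement of a discharge matching
#'
#' `100 * n_common / (n_common + n_a_only + n_b_only)`: the percentage of
#' discharges identified by both decompositions, with the standard
#' two-source denominator counting every distinct discharge once.
#'
#' @param m A `mu_matching`.
#' @return A list of class `mu_roa`: `n_common`, `n_a_only`, `n_b_only`,
#'   `roa` (percent).
#' @export
rate_of_agreement <- function(m) {
  n_common <- nrow(m$pairs)
  n_a <- length(m$unmatched_a)
  n_b <- length(m$unmatched_b)
  total <- n_common + n_a + n_b
  if (total == 0) abort("no discharges; rate of agreement undefined.")
  structure(list(n_common = n_common, n_a_only = n_a, n_b_only = n_b,
                 roa = 100 * n_common / total),
            class = "mu_roa")
}

#' Rate of agreement per contraction phase
#'
#' Assigns every discharge to a labelled phase (matched pairs by their
#' source-A time, unmatched discharges by their own time) and applies the
#' rate-of-agreement formula within each phase. Discharges outside all
#' phases are reported under `"outside"`.
#'
#' @param m A `mu_matching`.
#' @param phases Tibble with `phase`, `t_start`, `t_end` (disjoint,
#'   covering the analysis interval; intervals are `[t_start, t_end)`).
#' @return Tibble `phase`, `n_common`, `n_a_only`, `n_b_only`, `roa`.
#' @export
roa_by_phase <- function(m, phases) {
  assign_phase <- function(t) {
    out <- rep("outside", length(t))
    for (k in seq_len(nrow(phases))) {
      sel <- t >= phases$t_start[k] & t < phases$t_end[k]
      out[sel] <- phases$phase[k]
    }
    out
  }
  tab <- bind_rows(
    tibble(phase = assign_phase(m$pairs$time_a), kind = "common"),
    tibble(phase = assign_phase(m$unmatched_a), kind = "a_only"),
    tibble(phase = assign_phase(m$unmatched_b), kind = "b_only")
  )
  if (any(tab$phase == "outside"))
    warn("discharges outside all phases; reported under 'outside'.")
  levels <- unique(c(phases$phase, intersect("outside", tab$phase)))
  purrr::map_dfr(levels, function(ph) {
    sub <- tab[tab$phase == ph, ]
    nc <- sum(sub$kind == "common")
    na_ <- sum(sub$kind == "a_only")
    nb <- sum(sub$kind == "b_only")
    tot <- nc + na_ + nb
    tibble(phase = ph, n_common = nc, n_a_only = na_, n_b_only = nb,
           roa = if (tot > 0) 100 * nc / tot else NA_real_)
  })
}

#' Phase table of a trapezoidal ramp
#'
#' Convenience: the ramp-up / plateau / ramp-down intervals of a
#' [ramp_drive()] protocol.
#'
#' @param slope,plateau_level,plateau_dur As in [ramp_drive()].
#' @return Tibble `phase`, `t_start`, `t_end`.
#' @export
ramp_phases <- function(slope = 1, plateau_level = 10, plateau_dur = 10) {
  rise <- plateau_level / slope
  tibble(
    phase = c("ramp_up", "plateau", "ramp_down"),
    t_start = c(0, rise, rise + plateau_dur),
    t_end = c(rise, rise + plateau_dur, 2 * rise + plateau_dur)
  )
}

#' Spike-triggered average waveform
#'
#' Averages, per channel, the signal segments centred on each discharge,
#' estimating the unit's action-potential waveform as seen by the
#' multichannel recording. Triggers whose window would be clipped by the
#' signal edges are skipped and counted.
#'
#' @param emg A `mu_emg` tibble (`time_s` + channel columns).
#' @param times Trigger (discharge) times, seconds.
#' @param window_ms Full window length, milliseconds (symmetric about the
#'   trigger; default 50, i.e. +-25 ms).
#' @param min_triggers Minimum usable triggers.
#' @return A list of class `mu_sta`: `waveform` (channels x samples
#'   matrix), `lags_ms`, `n_triggers`, `n_skipped`, `window_ms`.
#' @export
sta_waveform <- function(emg, times, window_ms = 50, min_triggers = 10) {
  fs <- attr(emg, "fs")
  if (is.null(fs)) abort("`emg` must carry an `fs` attribute.")
  chans <- setdiff(names(emg), "time_s")
  half <- round(window_ms / 2000 * fs)
  t0 <- emg$time_s[1]
  n <- nrow(emg)
  centers <- round((times - t0) * fs) + 1
  usable <- centers - half >= 1 & centers + half <= n
  n_skipped <- sum(!usable)
  centers <- centers[usable]
  if (length(centers) < min_triggers)
    abort(sprintf("only %d usable triggers (minimum %d).",
                  length(centers), min_triggers))
  offs <- -half:half
  wav <- matrix(0, nrow = length(chans), ncol = length(offs),
                dimnames = list(chans, NULL))
  for (ci in seq_along(chans)) {
    x <- emg[[chans[ci]]]
    seg <- vapply(centers, function(c0) x[c0 + offs], numeric(length(offs)))
    wav[ci, ] <- rowMeans(seg)
  }
  structure(list(waveform = wav, lags_ms = offs / fs * 1000,
                 n_triggers = length(centers), n_skipped = n_skipped,
                 window_ms = window_ms),
            class = "mu_sta")
}

#' Pair units across two sources by waveform correlation
#'
#' Correlates channel-concatenated, per-waveform mean-removed
#' spike-triggered averages between the two sources and accepts pairs
#' above `corr_thresh`, resolved one-to-one greedily by descending
#' correlation. Two units paired this way are taken as commonly detected
#' by both decompositions.
#'
#' @param wavs_a,wavs_b Named lists of `mu_sta` objects (same channel and
#'   window layout).
#' @param corr_thresh Acceptance threshold on the correlation coefficient
#'   (default 0.9).
#' @return Tibble `unit_a`, `unit_b`, `correlation` (possibly empty).
#' @export
match_units <- function(wavs_a, wavs_b, corr_thresh = 0.9) {
  flat <- function(w) {
    v <- as.vector(t(w$waveform))
    v - mean(v)
  }
  fa <- purrr::map(wavs_a, flat)
  fb <- purrr::map(wavs_b, flat)
  lens <- unique(c(lengths(fa), lengths(fb)))
  if (length(lens) != 1)
    abort("waveform layouts differ between sources.")
  grid <- tidyr::expand_grid(unit_a = names(fa), unit_b = names(fb))
  grid$correlation <- purrr::map2_dbl(grid$unit_a, grid$unit_b,
                                      function(ua, ub) cor(fa[[ua]], fb[[ub]]))
  cand <- grid %>%
    filter(.data$correlation >= corr_thresh) %>%
    arrange(desc(.data$correlation))
  taken_a <- character(0); taken_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$unit_a[i] %in% taken_a) && !(cand$unit_b[i] %in% taken_b)) {
      keep[i] <- TRUE
      taken_a <- c(taken_a, cand$unit_a[i])
      taken_b <- c(taken_b, cand$unit_b[i])
    }
  }
  cand[keep, ]
}
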