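# Independent brute-force oracles used to cross-check the implementation.

# First buffer index at which `hold` consecutive TRUE values end, scanning
# every window explicitly; NA when no such window exists.
brute_hit_scan <- function(flags, hold) {
  n <- length(flags)
  for (b in hold:n) {
    if (b >= hold && all(flags[(b - hold + 1):b])) return(b)
  }
  NA_integer_
}

# Count maximal runs of TRUE with length >= min_len by explicit scanning.
brute_run_count <- function(flags, min_len) {
  count <- 0L
  run <- 0L
  for (f in c(flags, FALSE)) {
    if (f) run <- run + 1L
    else {
      if (run >= min_len) count <- count + 1L
      run <- 0L
    }
  }
  count
}

# Exhaustive nearest-miss: mean position of every k-window, earliest
# minimiser of the distance to `center`.
brute_nearest_miss <- function(x, y, center, k) {
  n <- length(x)
  best <- NULL
  for (i in seq_len(n - k + 1)) {
    mx <- mean(x[i:(i + k - 1)])
    my <- mean(y[i:(i + k - 1)])
    d <- sqrt((mx - center[1])^2 + (my - center[2])^2)
    if (is.null(best) || d < best$d - 1e-15)
      best <- list(x = mx, y = my, d = d, start = i)
  }
  best
}

# Maximum one-to-one matching count between two sorted time series with
# tolerance `tol` (seconds): non-crossing DP, optimal for interval
# tolerance matching of sorted sequences.
brute_match_count <- function(a, b, tol) {
  na <- length(a); nb <- length(b)
  f <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      best <- max(f[i, j + 1], f[i + 1, j])
      if (abs(a[i] - b[j]) <= tol + 1e-12)
        best <- max(best, f[i, j] + 1L)
      f[i + 1, j + 1] <- best
    }
  }
  f[na + 1, nb + 1]
}

# Exhaustive onset scan: earliest spike i with isi(i) <= 1/rate_thresh.
brute_onset <- function(times, rate_thresh = 5) {
  if (length(times) < 2) return(NA_real_)
  for (i in seq_len(length(times) - 1)) {
    if (times[i + 1] - times[i] <= 1 / rate_thresh + 1e-12) return(times[i])
  }
  NA_real_
}

# Exhaustive offset scan: last spike followed by >= silence of quiet.
brute_offset <- function(times, silence, horizon_end) {
  out <- NA_real_
  for (i in seq_along(times)) {
    gap <- if (i < length(times)) times[i + 1] - times[i]
           else horizon_end - times[i]
    if (gap >= silence - 1e-12) out <- times[i]
  }
  out
}
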