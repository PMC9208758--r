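test_that("discharge matching pairs nearest candidates within tolerance", {
  a <- c(0.1, 0.2, 0.3)
  b <- c(0.1005, 0.2, 0.45)
  m <- match_discharges(a, b, tol_ms = 1)
  expect_equal(m$pairs$time_a, c(0.1, 0.2))
  expect_equal(m$pairs$time_b, c(0.1005, 0.2))
  expect_equal(m$unmatched_a, 0.3)
  expect_equal(m$unmatched_b, 0.45)
  # identical trains match completely
  mi <- match_discharges(a, a)
  expect_equal(nrow(mi$pairs), 3)
  expect_length(mi$unmatched_a, 0)
  # zero tolerance keeps only exact coincidences
  m0 <- match_discharges(a, b, tol_ms = 0)
  expect_equal(m0$pairs$time_a, 0.2)
})

test_that("rate of agreement follows the two-source formula", {
  a <- seq(0.1, 10, 0.1)
  expect_equal(rate_of_agreement(match_discharges(a, a))$roa, 100)
  m <- list(pairs = tibble::tibble(time_a = c(1, 2), time_b = c(1, 2)),
            unmatched_a = 3, unmatched_b = 4, tol_ms = 1)
  class(m) <- "mu_matching"
  expect_equal(rate_of_agreement(m)$roa, 50)  # 2 / (2 + 1 + 1)
  empty <- list(pairs = tibble::tibble(time_a = numeric(), time_b = numeric()),
                unmatched_a = numeric(), unmatched_b = numeric(), tol_ms = 1)
  class(empty) <- "mu_matching"
  expect_error(rate_of_agreement(empty), "no discharges")
})

test_that("RoA is symmetric and decreases when a pair is broken", {
  set.seed(7)
  a <- sort(runif(200, 0, 60))
  b <- corrupt_spike_train(a, jitter_sd_ms = 0.2, p_miss = 0.1,
                           p_extra = 0.1, seed = 8)
  roa_ab <- rate_of_agreement(match_discharges(a, b))$roa
  roa_ba <- rate_of_agreement(match_discharges(b, a))$roa
  expect_equal(roa_ab, roa_ba)
  # removing a matched pair and re-adding both spikes unmatched lowers RoA
  m <- match_discharges(a, b)
  broken <- list(pairs = m$pairs[-1, ],
                 unmatched_a = c(m$unmatched_a, m$pairs$time_a[1]),
                 unmatched_b = c(m$unmatched_b, m$pairs$time_b[1]),
                 tol_ms = m$tol_ms)
  class(broken) <- "mu_matching"
  expect_lt(rate_of_agreement(broken)$roa, roa_ab)
  # common time shifts do not change the matching
  m_shift <- match_discharges(a + 5, b + 5)
  expect_equal(nrow(m_shift$pairs), nrow(m$pairs))
})

test_that("greedy matching equals optimal matching when ISIs exceed 2 tol", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    a <- cumsum(runif(n, 0.05, 0.3))  # ISIs >= 50 ms >> 2 ms
    b <- corrupt_spike_train(a, jitter_sd_ms = 0.4, p_miss = 0.15,
                             p_extra = 0.15, seed = i)
    m <- match_discharges(a, b, tol_ms = 1)
    expect_equal(nrow(m$pairs), brute_match_count(a, b, 0.001))
  }
})

test_that("corrupted-train RoA approaches its closed-form expectation", {
  a <- seq(0.05, 300, by = 0.1)  # 3000 discharges at 10 pps
  b <- corrupt_spike_train(a, jitter_sd_ms = 0.3, p_miss = 0.05,
                           p_extra = 0.02, seed = 9)
  roa <- rate_of_agreement(match_discharges(a, b, tol_ms = 1))$roa
  expect_lt(abs(roa - 100 * 0.95 / 1.02), 1)
})

test_that("per-phase RoA isolates where the corruption lives", {
  phases <- ramp_phases(1, 10, 20)
  expect_equal(phases$t_start, c(0, 10, 30))
  expect_equal(phases$t_end, c(10, 30, 40))  # symmetric 10 s decline
  a <- seq(0.05, 39.95, by = 0.1)
  # corruption confined to the ramp-up: other phases stay at 100%
  b <- c(corrupt_spike_train(a[a < 10], jitter_sd_ms = 0, p_miss = 0.3,
                             p_extra = 0, seed = 2), a[a >= 10])
  per <- roa_by_phase(match_discharges(a, b), phases)
  expect_lt(per$roa[per$phase == "ramp_up"], 100)
  expect_equal(per$roa[per$phase == "plateau"], 100)
  expect_equal(per$roa[per$phase == "ramp_down"], 100)
  # uniform corruption: phases agree with the global value
  bu <- corrupt_spike_train(a, jitter_sd_ms = 0.2, p_miss = 0.1,
                            p_extra = 0.05, seed = 3)
  mu_ <- match_discharges(a, bu)
  global <- rate_of_agreement(mu_)$roa
  per_u <- roa_by_phase(mu_, phases)
  expect_true(all(abs(per_u$roa - global) < 6))
  # discharges outside the phase table are reported
  short <- phases[1:2, ]
  expect_warning(roa_by_phase(mu_, short), "outside")
})

test_that("spike-triggered averaging recovers embedded waveforms", {
  fs <- 2048
  t <- seq(0, 60, by = 1 / fs)
  pulse <- c(0, 1, 2, 1, 0, -1, -2, -1, 0)
  spikes <- seq(1, 59, by = 0.25)
  x <- numeric(length(t))
  idx <- round(spikes * fs) + 1
  for (k in -4:4) x[idx + k] <- x[idx + k] + pulse[k + 5]
  emg <- tibble::tibble(time_s = t, ch1 = x, ch2 = 2 * x)
  attr(emg, "fs") <- fs
  sta <- sta_waveform(emg, spikes, window_ms = 10)
  expect_equal(nrow(sta$waveform), 2)
  mid <- (ncol(sta$waveform) + 1) / 2
  expect_equal(sta$waveform[1, mid + (-4:4)], pulse, tolerance = 1e-9)
  expect_equal(sta$waveform[2, ], 2 * sta$waveform[1, ], tolerance = 1e-9)
  # averaging suppresses independent noise roughly as 1/sqrt(n)
  set.seed(10)
  noise_sd <- 0.5
  emg_n <- emg; emg_n$ch1 <- x + rnorm(length(t), sd = noise_sd)
  sta_n <- sta_waveform(emg_n, spikes, window_ms = 10)
  resid <- sta_n$waveform[1, ] - sta$waveform[1, ]
  expect_lt(abs(sd(resid) / (noise_sd / sqrt(sta_n$n_triggers)) - 1), 0.3)
  # edge triggers are skipped and counted
  sta_e <- sta_waveform(emg, c(0.001, spikes), window_ms = 10)
  expect_equal(sta_e$n_skipped, 1)
  expect_error(sta_waveform(emg, c(30), window_ms = 10), "triggers")
})

test_that("unit pairing accepts only high-correlation waveforms one-to-one", {
  base <- sin(seq(0, 2 * pi, length.out = 51))
  orth <- cos(seq(0, 2 * pi, length.out = 51))
  mk <- function(v) structure(list(waveform = matrix(v, nrow = 1),
                                   lags_ms = seq_along(v), n_triggers = 50,
                                   window_ms = 50), class = "mu_sta")
  same <- match_units(list(u1 = mk(base), u2 = mk(orth)),
                      list(v1 = mk(base), v2 = mk(orth)))
  expect_equal(nrow(same), 2)
  expect_true(all(same$correlation > 0.999))
  expect_equal(same$unit_b[same$unit_a == "u1"], "v1")
  none <- match_units(list(u1 = mk(base)), list(v1 = mk(orth)))
  expect_equal(nrow(none), 0)
  # noisy copy among low-correlation decoys pairs exactly once
  set.seed(12)
  noisy <- base + rnorm(51, sd = 0.12)
  stopifnot(cor(base, noisy) > 0.9)
  decoy <- rnorm(51)
  res <- match_units(list(u1 = mk(base)),
                     list(v1 = mk(noisy), v2 = mk(decoy)))
  expect_equal(nrow(res), 1)
  expect_equal(res$unit_b, "v1")
  expect_error(match_units(list(u1 = mk(base)),
                           list(v1 = mk(base[1:20]))), "layout")
})
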