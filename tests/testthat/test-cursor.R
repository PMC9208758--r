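test_that("buffer rates count spikes per 125 ms block", {
  cfg <- buffer_config()
  r <- buffer_rates(c(0.01, 0.05, 0.10), cfg, horizon_s = 0.25)
  expect_equal(r$rate, c(24, 0))          # 3 spikes / 0.125 s, then empty
  # boundary spike belongs to the later buffer
  rb <- buffer_rates(0.125, cfg, horizon_s = 0.5)
  expect_equal(rb$rate, c(0, 8, 0, 0))
  # uniform 10 pps: counts over any whole second sum to 10
  ru <- buffer_rates(seq(0, 0.9, 0.1), cfg, horizon_s = 1)
  expect_equal(sum(ru$rate) * cfg$buffer_s, 10)
  expect_true(all(ru$rate %in% c(8, 16)))  # per-buffer counts 1 or 2
})

test_that("the cascaded trailing means have a 13-buffer step response", {
  cfg <- buffer_config()
  k <- 20
  rates <- tibble::tibble(buffer = 1:60,
                          rate1 = c(rep(0, k), rep(10, 40)),
                          rate2 = 0)
  st <- cursor_positions(rates, ref_rates = c(10, 10), cfg = cfg,
                         init = "zero")
  support <- cfg$rate_window_buffers + cfg$cursor_ma_buffers - 1  # 13
  expect_lt(st$x[k + support - 1], 1)
  expect_equal(st$x[k + support], 1.0)
  expect_true(all(st$x[(k + support):60] == 1.0))
  expect_true(all(st$y == 0))              # silent MU stays at the axis
  # impulse response support is exactly 13 buffers
  imp <- tibble::tibble(buffer = 1:40,
                        rate1 = c(rep(0, 5), 10, rep(0, 34)), rate2 = 0)
  sti <- cursor_positions(imp, ref_rates = c(10, 10), cfg = cfg, init = "zero")
  expect_equal(sum(sti$x > 0), support)
})

test_that("truncated warm-up keeps a constant input constant", {
  rates <- tibble::tibble(buffer = 1:20, rate1 = 10, rate2 = 5)
  st <- cursor_positions(rates, ref_rates = c(10, 10),
                         gains = c(1.15, 1.16))
  expect_true(all(abs(st$x - 1.15) < 1e-12))
  expect_true(all(abs(st$y - 0.58) < 1e-12))
})

test_that("cursor pipeline is linear in the rates", {
  set.seed(21)
  rates <- tibble::tibble(buffer = 1:50, rate1 = runif(50, 0, 20),
                          rate2 = runif(50, 0, 20))
  st1 <- cursor_positions(rates, ref_rates = c(10, 12))
  rates3 <- dplyr::mutate(rates, rate1 = 3 * rate1, rate2 = 3 * rate2)
  st3 <- cursor_positions(rates3, ref_rates = c(10, 12))
  expect_equal(st3$x, 3 * st1$x, tolerance = 1e-12)
  expect_equal(st3$y, 3 * st1$y, tolerance = 1e-12)
  expect_error(cursor_positions(rates, ref_rates = c(0, 10)), "ref_rates")
})

test_that("the region test classifies target, wedge and cropped zones", {
  g1 <- target_geometry("TI")
  expect_equal(point_region(1.0, 0, g1), "target")
  expect_equal(point_region(0.3, 0, g1), "neither")   # inside the 0.4 crop
  expect_equal(point_region(0.5, 0.2, g1), "neither") # 21.8 deg > 5.74 deg
  expect_equal(point_region(0.9, 0, g1), "target")    # boundary inside
  expect_equal(point_region(0.5, 0, g1), "angle")
  expect_equal(point_region(0, 0, g1), "neither")     # origin
  # wedge half-angle: asin(0.1) = 5.74 deg for TI
  expect_equal(g1$wedge_half_angle, asin(0.1) * 180 / pi)
  g2 <- target_geometry("TII")
  expect_equal(g2$wedge_half_angle, asin(0.1 / sqrt(2)) * 180 / pi)
  expect_equal(point_region(0.5, 0.5, g2), "angle")
})

test_that("target discs lie inside their angle wedges", {
  for (tg in c("TI", "TII", "TIII")) {
    g <- target_geometry(tg)
    a <- seq(0, 2 * pi, length.out = 400)
    px <- g$center[1] + 0.0999 * cos(a)
    py <- g$center[2] + 0.0999 * sin(a)
    r <- sqrt(px^2 + py^2)
    ang <- acos(pmin(1, (px * g$center[1] + py * g$center[2]) /
                       (r * sqrt(sum(g$center^2))))) * 180 / pi
    expect_true(all(r >= g$inner_crop))
    expect_true(all(ang <= g$wedge_half_angle + 1e-9))
  }
})

test_that("trial rules grant hits at the 7th consecutive buffer", {
  cfg <- buffer_config()
  # in-target from buffer 40 onward
  x <- c(rep(0.5, 39), rep(1, 121)); y <- rep(0, 160)
  tr <- trial_from_xy(x, y, "TI")
  expect_equal(tr$target_hit_buffer, 46)
  expect_equal(tr$n_buffers, 46)
  expect_equal(tr$outcome, "target_hit")
  # 6-buffer excursion: no hit
  x2 <- c(rep(0.5, 39), rep(1, 6), rep(0.5, 115))
  tr2 <- trial_from_xy(x2, y, "TI")
  expect_true(is.na(tr2$target_hit_buffer))
  expect_equal(tr2$outcome, "timeout")
  expect_equal(tr2$n_buffers, cfg$timeout_buffers)
  # angle hit then target hit in one trial; wedge includes the target disc
  x3 <- c(rep(0.6, 10), rep(1, 150))
  tr3 <- trial_from_xy(x3, y, "TI")
  expect_equal(tr3$angle_hit_buffer, 7)
  expect_equal(tr3$target_hit_buffer, 17)
  # short stream without hit is flagged truncated
  tr4 <- trial_from_xy(rep(0.5, 20), rep(0, 20), "TI")
  expect_equal(tr4$outcome, "truncated")
})

test_that("hit detection equals the exhaustive 7-buffer window scan", {
  cfg <- buffer_config()
  set.seed(33)
  g <- target_geometry("TI")
  for (i in 1:200) {
    n <- sample(20:60, 1)
    # sticky random walk near the target edge to produce runs
    x <- numeric(n); x[1] <- 0.9
    for (b in 2:n) x[b] <- x[b - 1] + sample(c(-0.05, 0, 0.05), 1)
    y <- rep(0, n)
    tr <- trial_from_xy(x, y, "TI", cfg)
    flags <- point_region(x, y, g) == "target"
    oracle <- brute_hit_scan(flags, cfg$hold_buffers)
    expect_identical(tr$target_hit_buffer, oracle)
  }
})

test_that("sessions randomise targets reproducibly and honour counts", {
  pair <- flat_pair(isi_cov = 0.1)
  policy <- function(target, pr, s) three_stage_drive(pr, dwell = 3, fs = 64)
  s1 <- run_session(pair, policy, ref_rates = c(12, 12), repeats = 2,
                    seed = 42)
  s2 <- run_session(pair, policy, ref_rates = c(12, 12), repeats = 2,
                    seed = 42)
  expect_identical(s1$info, s2$info)
  expect_equal(nrow(s1$info), 6)            # 3 targets x 2 repeats
  expect_setequal(unique(s1$info$target), c("TI", "TII", "TIII"))
})
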