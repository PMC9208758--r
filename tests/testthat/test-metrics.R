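test_that("raw performance matches closed forms", {
  cfg <- buffer_config()
  g1 <- target_geometry("TI")
  # origin-hold for the full timeout: 160 * ((1/sqrt(2))^2 + 1) = 240
  origin <- stream_from_xy(rep(0, 160), rep(0, 160))
  expect_equal(performance_raw(origin, g1), 240.0)
  # cursor at the centre contributes nothing
  center <- stream_from_xy(rep(1, 10), rep(0, 10))
  expect_equal(performance_raw(center, g1), 0)
  # single buffer at (0.5, 0): (0.5/sqrt(2))^2 + 0 = 0.125
  expect_equal(performance_raw(stream_from_xy(0.5, 0), g1), 0.125)
  # rss variant takes the per-buffer square root
  expect_equal(performance_raw(stream_from_xy(0.5, 0), g1, variant = "rss"),
               sqrt(0.125))
})

test_that("performance bounds reproduce the worst closed forms and a fast ideal", {
  cfg <- buffer_config()
  b1 <- performance_bounds("TI", cfg)
  expect_equal(b1$worst_raw, 240.0)
  b2 <- performance_bounds("TII", cfg)
  expect_equal(b2$worst_raw, 320.0)   # 160 * ((sqrt(2)/sqrt(2))^2 + 1)
  b3 <- performance_bounds("TIII", cfg)
  expect_equal(b3$worst_raw, 240.0)
  for (b in list(b1, b2, b3)) {
    expect_lt(b$best_raw, b$worst_raw)
    # ideal trajectory hits within step-response support + hold
    expect_lte(b$trial$target_hit_buffer, 13 + 7)
  }
})

test_that("normalisation is linear with clipped endpoints", {
  bounds <- list(best_raw = 10, worst_raw = 240)
  expect_equal(performance_normalized(240, bounds), 0)
  expect_equal(performance_normalized(10, bounds), 1)
  expect_equal(performance_normalized(125, bounds), 0.5)
  expect_equal(performance_normalized(500, bounds), 0)   # clipped
  expect_error(performance_normalized(1, list(best_raw = 5, worst_raw = 5)),
               "degenerate")
})

test_that("appending an off-centre buffer strictly increases raw", {
  g <- target_geometry("TI")
  set.seed(5)
  x <- runif(20); y <- runif(20)
  base <- performance_raw(stream_from_xy(x, y), g)
  worse <- performance_raw(stream_from_xy(c(x, 0.7), c(y, 0.1)), g)
  expect_gt(worse, base)
})

test_that("nearest miss finds the closest 875 ms window", {
  cfg <- buffer_config()
  tr <- trial_from_xy(rep(0.5, 160), rep(0, 160), "TI")
  nm <- nearest_miss(tr)
  expect_equal(c(nm$x, nm$y), c(0.5, 0))
  # far-then-near stream: the window sits in the near phase
  tr2 <- trial_from_xy(c(rep(0.2, 80), rep(0.7, 80)), rep(0, 160), "TI")
  nm2 <- nearest_miss(tr2)
  expect_gte(nm2$window_start, 80)
  expect_equal(nm2$x, 0.7)
  # contract: not applicable to hit trials
  hit <- trial_from_xy(rep(1, 20), rep(0, 20), "TI")
  expect_error(nearest_miss(hit), "without a target hit")
})

test_that("nearest miss equals the exhaustive window scan", {
  cfg <- buffer_config()
  set.seed(44)
  g <- target_geometry("TI")
  for (i in 1:200) {
    n <- sample(8:40, 1)
    x <- runif(n, 0, 0.8); y <- runif(n, 0, 0.8)
    tr <- trial_from_xy(x, y, "TI", cfg)
    if (!is.na(tr$target_hit_buffer)) next
    nm <- nearest_miss(tr, cfg = cfg)
    oracle <- brute_nearest_miss(x, y, g$center, cfg$hold_buffers)
    expect_equal(nm$x, oracle$x, tolerance = 1e-12)
    expect_equal(nm$distance, oracle$d, tolerance = 1e-12)
    expect_equal(nm$window_start, oracle$start)
  }
})

test_that("unintended hits count long excursions with re-entries", {
  # trajectory crossing the TII wedge for 10 buffers en route to TIII
  x <- c(rep(0.5, 10), rep(0, 150))
  y <- c(rep(0.5, 10), rep(1, 150))
  tr <- trial_from_xy(x, y, "TIII")
  u <- unintended_hits(tr)
  expect_gte(u$count[u$target == "TII" & u$region == "angle"], 1)
  # 6-buffer excursion does not count
  tr2 <- trial_from_xy(c(rep(1, 6), rep(0.2, 154)), rep(0, 160), "TIII")
  u2 <- unintended_hits(tr2)
  expect_equal(u2$count[u2$target == "TI" & u2$region == "target"], 0)
  # two separated 7-buffer excursions into TI count twice
  x3 <- c(rep(1, 7), rep(0.2, 7), rep(1, 7), rep(0.2, 139))
  u3 <- unintended_hits(trial_from_xy(x3, rep(0, 160), "TIII"))
  expect_equal(u3$count[u3$target == "TI" & u3$region == "target"], 2)
})

test_that("excursion counting equals the brute-force run scan", {
  cfg <- buffer_config()
  set.seed(55)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    x <- round(runif(n, 0.7, 1.2), 1); y <- rep(0, n)
    tr <- trial_from_xy(x, y, "TIII", cfg)
    u <- unintended_hits(tr, cfg)
    g <- target_geometry("TI")
    flags <- point_region(x, y, g) == "target"
    expect_equal(u$count[u$target == "TI" & u$region == "target"],
                 brute_run_count(flags, cfg$hold_buffers))
  }
})

test_that("direct movements require strict silence of the other unit", {
  tr <- trial_from_xy(rep(1, 20), rep(0, 20), "TI")
  expect_true(classify_direct(tr, times_mu1 = c(0.1, 0.2), times_mu2 = numeric(0)))
  tr3 <- trial_from_xy(rep(0, 20), rep(1, 20), "TIII")
  expect_false(classify_direct(tr3, times_mu1 = 0.5, times_mu2 = c(0.1, 0.2)))
  # TII and no-hit trials are not applicable
  tr2 <- trial_from_xy(rep(1, 20), rep(1, 20), "TII")
  expect_true(is.na(classify_direct(tr2, 0.1, 0.1)))
  miss <- trial_from_xy(rep(0.2, 160), rep(0.2, 160), "TI")
  expect_true(is.na(classify_direct(miss, 0.1, 0.1)))
})

test_that("stage forces recover the three-stage drive levels", {
  pair <- flat_pair()
  drv <- three_stage_drive(pair, fs = 256)
  stages <- attr(drv, "stages")
  tr <- run_closed_loop_trial(pair, function(target, pr, s) drv, "TIII",
                              ref_rates = c(12, 12), trial_seed = 1)
  expect_equal(tr$outcome, "target_hit")
  cfg <- buffer_config()
  rest_offset <- floor(cfg$rest_s / cfg$buffer_s) * cfg$buffer_s
  force <- simulate_force(drv, noise_sd = 0)
  force$time_s <- force$time_s - rest_offset   # trial clock
  sf <- stage_forces(tr, force, cfg)
  expect_equal(sf$f1, stages$level[1], tolerance = 0.3)
  expect_equal(sf$f2, stages$level[2], tolerance = 0.3)
  expect_false(is.na(sf$f3))
  # direct TIII trials carry no both-active epoch
  direct <- trial_from_xy(rep(0, 30), rep(1, 30), "TIII")
  direct$stream$rbar1 <- 0; direct$stream$rbar2 <- 12
  expect_warning(sf2 <- stage_forces(direct, force, cfg), "direct|both-active")
  expect_true(is.na(sf2$f1))
})

test_that("learning correlation is a rank trend", {
  expect_equal(learning_correlation(seq(0.1, 0.9, length.out = 10)), 1.0)
  expect_equal(learning_correlation(seq(0.9, 0.1, length.out = 10)), -1.0)
  set.seed(66)
  expect_lt(abs(learning_correlation(runif(1000))), 0.1)
  expect_warning(r0 <- learning_correlation(rep(0.5, 10)), "constant")
  expect_equal(r0, 0)
  expect_error(learning_correlation(c(1, 2)), "3 trials")
})
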