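test_that("finite-difference derivative is exact for linear signals", {
  tr <- signal_trace(rep(3.7, 100), fs = 1000)
  expect_true(all(compute_derivative(tr)$values == 0))
  # s[i] = 2 i at fs = 1: derivative identically 2, boundaries included
  tr2 <- signal_trace(2 * (0:49), fs = 1)
  expect_true(all(compute_derivative(tr2)$values == 2))
  expect_error(compute_derivative(signal_trace(c(0, 1), fs = 1)), "too short")
})

test_that("central differences meet the truncation bound on a smooth sine", {
  fs <- 115100; f0 <- 50; A <- 1
  t <- (0:(fs %/% 10)) / fs
  tr <- signal_trace(A * sin(2 * pi * f0 * t), fs)
  d <- compute_derivative(tr)$values
  true_d <- 2 * pi * f0 * A * cos(2 * pi * f0 * t)
  interior <- 2:(length(t) - 1)
  bound <- (2 * pi * f0)^3 / (6 * fs^2) * A       # h^2 f'''/6
  expect_lt(max(abs(d[interior] - true_d[interior])), bound * 1.01)
  # boundary one-sided differences are first-order accurate
  edge_bound <- (2 * pi * f0)^2 / (2 * fs) * A    # h f''/2
  expect_lt(abs(d[length(t)] - true_d[length(t)]), edge_bound * 1.01)
})

test_that("MAD auto-threshold estimates the noise scale robustly", {
  set.seed(11)
  d <- derivative_trace(rnorm(1e5, 0, 2.5), fs = 1000)
  th <- auto_threshold(d, k = 5)
  expect_lt(abs(th / 5 - 2.5) / 2.5, 0.05)
  # sparse large events inflate the scale by < 1%
  spiked <- d
  spiked$values[sample.int(1e5, 500)] <- 100
  expect_lt(abs(auto_threshold(spiked, 5) - th) / th, 0.01)
  # exact homogeneity
  d10 <- derivative_trace(10 * d$values, fs = 1000)
  expect_equal(auto_threshold(d10, 5), 10 * th, tolerance = 1e-12)
  # degenerate all-zero derivative refuses to run
  dz <- derivative_trace(numeric(1000), fs = 1000)
  thz <- auto_threshold(dz, 5)
  expect_true(isTRUE(attr(thz, "degenerate")))
  tr <- signal_trace(numeric(1000), fs = 1000)
  expect_error(detect_events(dz, tr, detector_config()), "degenerate")
})

test_that("a noiseless bipolar pulse yields one event at the analytic extrema", {
  A <- 10e-6; delta <- 1.08e-3; sigma <- delta / 4; fs <- 115100
  tr <- pulse_trace(0.05, A = A, delta = delta, sigma = sigma, fs = fs)
  ev <- run_pipeline(tr, manual_cfg(tr, delta = delta))
  expect_identical(nrow(ev), 1L)
  pk <- bigaussian_peaks(A, delta, sigma)
  expect_lt(abs(ev$t_pos_s - (0.05 - pk$t_offset_s)) * fs, 1)
  expect_lt(abs(ev$t_neg_s - (0.05 + pk$t_offset_s)) * fs, 1)
  expect_equal(ev$dV_V, pk$p2p_V, tolerance = 1e-3)
  # landmark consistency: peak value dominates the window edges
  expect_gt(ev$v_pos_V, tr$samples[ev$left_idx])
  expect_gt(ev$v_pos_V, tr$samples[ev$right_idx])

  tr2 <- pulse_trace(c(0.05, 0.07), A = A, delta = delta, sigma = sigma)
  ev2 <- run_pipeline(tr2, manual_cfg(tr2, delta = delta))
  expect_identical(nrow(ev2), 2L)
  expect_true(ev2$t_pos_s[1] < ev2$t_pos_s[2])
})

test_that("detection is exactly invariant to constant offsets", {
  set.seed(21)
  cfg <- quick_config(duration_s = 1, D_um = 4)
  cfg$seed <- 17
  st <- synthesize_stream(cfg, keep_components = FALSE)
  dcfg <- detector_config_for(cfg)
  ev1 <- run_pipeline(st$trace, dcfg)
  shifted <- signal_trace(st$trace$samples + 1, st$trace$fs)
  ev2 <- run_pipeline(shifted, dcfg)
  expect_identical(ev1[c("left_idx", "pos_idx", "neg_idx", "right_idx")],
                   ev2[c("left_idx", "pos_idx", "neg_idx", "right_idx")])
})

test_that("an all-zero trace produces no events under a manual threshold", {
  tr <- signal_trace(numeric(5000), fs = 1000)
  cfg <- detector_config(threshold_V_s = 1e-6)
  expect_identical(nrow(run_pipeline(tr, cfg)), 0L)
})

test_that("single-pass grouping matches an exhaustive brute-force scan", {
  fs <- 115100
  for (seed in 1:6) {
    set.seed(seed)
    n <- 8000
    nz <- filter_noise(rnorm(n, 0, 1.3e-6), 4, 500, fs)
    t <- (seq_len(n) - 1) / fs
    s <- nz + bigaussian_pulse(t, 6e-7, 1.08e-3, 0.27e-3, 0.02) +
      bigaussian_pulse(t, 5e-7, 1.08e-3, 0.27e-3, 0.045)
    tr <- signal_trace(s, fs)
    d <- compute_derivative(tr)
    for (kk in c(2, 4)) {
      theta <- kk * mad(d$values)
      cfg <- detector_config(threshold_V_s = theta, min_lobe_samples = 3,
                             max_gap_s = 1.08e-3, refractory_s = 0)
      ev <- detect_events(d, tr, cfg)
      oracle <- brute_force_events(d$values, tr$samples, theta, 3,
                                   round(1.08e-3 * fs))
      got <- matrix(as.integer(c(ev$pos_idx, ev$neg_idx)), ncol = 2)
      expect_identical(got, matrix(as.integer(oracle), ncol = 2))
    }
  }
})

test_that("slow sinusoidal drift barely moves detected landmarks", {
  A <- 10e-6; delta <- 1.08e-3; fs <- 115100
  tr <- pulse_trace(c(0.05, 0.10, 0.16), A = A, delta = delta,
                    sigma = delta / 4, fs = fs, duration = 0.25)
  cfg <- manual_cfg(tr, delta = delta)
  ev <- run_pipeline(tr, cfg)
  t <- (seq_along(tr$samples) - 1) / fs
  drift <- 50e-6 * sin(2 * pi * 2 * t)
  evd <- run_pipeline(signal_trace(tr$samples + drift, fs), cfg)
  expect_identical(nrow(evd), nrow(ev))
  expect_true(all(abs(evd$pos_idx - ev$pos_idx) <= 2))
  expect_true(all(abs(evd$neg_idx - ev$neg_idx) <= 2))
})

test_that("inverted-polarity events are recovered with the polarity flag", {
  A <- 10e-6; delta <- 1.08e-3; fs <- 115100
  tr <- pulse_trace(0.05, A = A, delta = delta, sigma = delta / 4, fs = fs)
  mir <- signal_trace(rev(tr$samples), fs)   # time-mirrored: negative first
  cfg <- manual_cfg(tr, delta = delta)
  ev <- run_pipeline(tr, cfg)
  cfg_neg <- detector_config(threshold_V_s = cfg$threshold_V_s,
                             max_gap_s = delta, refractory_s = delta / 2,
                             polarity = "negative-first")
  evm <- run_pipeline(mir, cfg_neg)
  expect_identical(nrow(evm), 1L)
  expect_equal(evm$dV_V, ev$dV_V, tolerance = 1e-9)
  expect_equal(evm$dt_s, ev$dt_s, tolerance = 1e-9)
})

test_that("refractory merging keeps the larger of two colliding detections", {
  A <- 10e-6; delta <- 1.08e-3; fs <- 115100
  tr <- pulse_trace(c(0.05, 0.0508), A = c(A, A), delta = delta,
                    sigma = delta / 4, fs = fs)
  # two overlapping pulses produce nearby crossings; a generous refractory
  # collapses them to one reported event
  d <- compute_derivative(tr)
  cfg <- detector_config(threshold_V_s = 0.15 * max(abs(d$values)),
                         max_gap_s = delta, refractory_s = 2e-3)
  ev <- detect_events(d, tr, cfg)
  expect_lte(nrow(ev), 1L)
  cfg0 <- detector_config(threshold_V_s = cfg$threshold_V_s,
                          max_gap_s = delta, refractory_s = 0)
  expect_gte(nrow(detect_events(d, tr, cfg0)), nrow(ev))
})
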