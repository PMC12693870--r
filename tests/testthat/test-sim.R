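test_that("kinematics follow flow and geometry with exact unit conversion", {
  cfg <- sim_config(Q_uL_min = 2, channel_side_um = 30)
  kin <- derive_kinematics(cfg)
  # 2 uL/min = 3.333e7 um^3/s over a 900 um^2 cross-section
  expect_equal(kin$v_um_s, 2e9 / 60 / 900, tolerance = 1e-12)
  expect_equal(kin$v_um_s, 3.704e4, tolerance = 1e-3)
  expect_equal(kin$delta_s, 40 / kin$v_um_s, tolerance = 1e-12)
  expect_equal(kin$delta_s, 1.080e-3, tolerance = 1e-3)
  # doubling the flow halves the peak separation exactly
  kin2 <- derive_kinematics(sim_config(Q_uL_min = 4, channel_side_um = 30))
  expect_equal(kin2$delta_s, kin$delta_s / 2, tolerance = 1e-12)
  # transit across one 20 um electrode sets sigma = delta/4 here
  expect_equal(kin$sigma_s, kin$delta_s / 4, tolerance = 1e-12)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(Q_uL_min = -1), "positive")
  expect_error(sim_config(BW_Hz = 60000, fs_Sa_s = 115100), "Nyquist")
  expect_error(sim_config(n_stages = 0), "n_stages")
  expect_error(sim_config(CV = -0.1), "CV")
  expect_error(sim_config(drift = list(type = "wiggle", amplitude_V = 1)),
               "drift")
})

test_that("event sampling follows Poisson arrivals and the diameter law", {
  cfg <- quick_config(CV = 0, duration_s = 5)
  set.seed(1)
  ev <- sample_true_events(cfg)
  expect_true(all(ev$d_um == cfg$D_um))          # CV = 0 is degenerate
  expect_true(all(diff(ev$t0_s) >= 0))
  expect_true(all(ev$t_pos_s < ev$t_neg_s))
  expect_equal(ev$A_V, cfg$amp_coeff_V_per_um3 * ev$d_um^3)
  expect_equal(ev$t_neg_s - ev$t_pos_s, ev$delta_s)

  # arrival rate: rho * Q = 1e3/uL * 2 uL/min = 33.33/s; mean count over a
  # 30 s span is 1000. Empirical mean over 200 seeded draws within 3 SE.
  cfg30 <- sim_config(duration_s = 30)
  set.seed(7)
  counts <- replicate(200, nrow(sample_true_events(cfg30)))
  se <- sqrt(1000 / 200)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("the bipolar pulse renders exactly and superposes linearly", {
  A <- 10e-6; delta <- 1.08e-3; sigma <- delta / 4; t0 <- 0.05
  fs <- 115100; n <- round(0.1 * fs)
  t <- (seq_len(n) - 1) / fs
  y <- bigaussian_pulse(t, A, delta, sigma, t0)
  # odd symmetry about the centre: zero at t0
  expect_equal(bigaussian_pulse(t0, A, delta, sigma, t0), 0)
  # delta = 4 sigma: extremum ~ A (1 - e^-8), within grid interpolation
  expect_equal(max(y), A * (1 - exp(-8)), tolerance = 1e-3)
  # antisymmetric lobes integrate to zero
  expect_lt(abs(sum(y) / fs), 1e-6 * A * sigma)

  ev1 <- list(t0_s = 0.03, A_V = A, delta_s = delta, sigma_s = sigma)
  ev2 <- list(t0_s = 0.07, A_V = 2 * A, delta_s = delta, sigma_s = sigma)
  r1 <- render_event(ev1, n, fs)
  r2 <- render_event(ev2, n, fs)
  # rendering a two-event list equals summing the separate renders
  tr2 <- rbind(make_truth(0.03, A = A, delta = delta, sigma = sigma),
               make_truth(0.07, A = 2 * A, delta = delta, sigma = sigma))
  both <- pulsekit:::render_events(tr2, n, fs)
  expect_equal(both, r1 + r2, tolerance = 1e-12)

  expect_warning(out <- render_event(list(t0_s = 5, A_V = A, delta_s = delta,
                                          sigma_s = sigma), n, fs),
                 "outside")
  expect_true(all(out == 0))
})

test_that("the low-pass cascade hits its design bandwidth", {
  fs <- 115100; BW <- 500; n_st <- 4
  # unity DC gain: constant input reproduced in steady state
  const <- filter_noise(rep(1, 20000), n_st, BW, fs = fs)
  expect_equal(const[20000], 1, tolerance = 1e-6)
  # sine probe at BW attenuated by -3 dB (+/- 0.2 dB)
  t <- (0:(2 * fs)) / fs
  y <- filter_noise(sin(2 * pi * BW * t), n_st, BW, fs = fs)
  steady <- y[t > 1]
  gain_db <- 20 * log10((max(steady) - min(steady)) / 2)
  expect_lt(abs(gain_db - (-3.0103)), 0.2)
  expect_error(filter_noise(rnorm(100), 4, 6e4, fs = fs), "Nyquist")
})

test_that("filtered noise loses power, monotonically in bandwidth", {
  set.seed(42)
  w <- rnorm(4e5, 0, 1.3e-6)
  sds <- sapply(c(100, 300, 500, 1000), function(bw)
    sd(filter_noise(w, 4, bw, fs = 115100)))
  expect_true(all(sds < 1.3e-6))
  expect_true(all(diff(sds) > 0))
})

test_that("noise spectrum rolls off like an n-pole cascade", {
  fs <- 20000; BW <- 500
  set.seed(3)
  w <- rnorm(2^17)
  for (n_st in c(1L, 4L)) {
    y <- filter_noise(w, n_st, BW, fs = fs)
    p <- Mod(fft(y))^2
    f <- (seq_along(p) - 1) * fs / length(p)
    plateau <- mean(p[f > 10 & f < BW / 4])
    hi <- mean(p[f > 10 * BW * 0.9 & f < 10 * BW * 1.1])
    drop_db <- 10 * log10(plateau / hi)
    expect_gt(drop_db, n_st * 6 - 3 - 3)   # loose n-pole roll-off bound
  }
})

test_that("synthesized streams decompose exactly and are reproducible", {
  cfg <- quick_config(duration_s = 0.5,
                      drift = list(type = "sine", amplitude_V = 5e-6))
  cfg$seed <- 99
  st <- synthesize_stream(cfg)
  expect_equal(length(st$trace$samples), round(0.5 * 115100))
  with_comp <- st$components
  scale <- max(abs(st$trace$samples))
  expect_lt(max(abs(with_comp$e + with_comp$b + with_comp$n -
                    st$trace$samples)), 1e-12 * scale)
  expect_true(all(st$truth$t0_s >= 0 & st$truth$t0_s <= cfg$duration_s))
  st2 <- synthesize_stream(cfg)
  expect_identical(st$trace$samples, st2$trace$samples)
  expect_identical(st$truth, st2$truth)

  # zero noise, no drift: the trace is the exact event superposition
  cfg0 <- quick_config(duration_s = 0.5, sigmaN_V = 0)
  cfg0$seed <- 5
  st0 <- synthesize_stream(cfg0)
  expect_identical(st0$trace$samples, st0$components$e)
})

test_that("the default 30 s stream has the expected size and event count", {
  cfg <- sim_config(seed = 12)
  st <- synthesize_stream(cfg, keep_components = FALSE)
  expect_identical(length(st$trace$samples), 3453000L)
  # Poisson(1000): 5 sd corridor
  expect_gt(nrow(st$truth), 1000 - 5 * sqrt(1000))
  expect_lt(nrow(st$truth), 1000 + 5 * sqrt(1000))
})
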