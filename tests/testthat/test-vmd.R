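test_that("single tone is localized at the periodogram peak", {
  t <- seq_len(1024)
  for (alpha in c(500, 2000)) {
    s <- eeg_signal(cos(2 * pi * 0.1 * t), fs = 250)
    m <- vmd_decompose(s, vmd_config(K = 1, alpha = alpha, gamma = 0))
    expect_lt(abs(m$center_freqs[1] - periodogram_peak(s$samples)), 0.005)
    expect_true(m$converged)
  }
  # localization stays tight at both penalty levels (the recovered center
  # converges to the tone; at this noiseless scale both are ~1e-4 off)
  dev <- vapply(c(500, 2000), function(a) {
    m <- vmd_decompose(eeg_signal(cos(2 * pi * 0.1 * t), 250),
                       vmd_config(K = 1, alpha = a))
    abs(m$center_freqs[1] - 0.1)
  }, numeric(1))
  expect_true(all(dev < 1e-3))
})

test_that("zero signal yields zero modes with the 0/0 convention", {
  m <- vmd_decompose(eeg_signal(rep(0, 256), 250), vmd_config(K = 1))
  expect_equal(max(abs(m$modes)), 0)
  expect_equal(m$center_freqs, 0)
  expect_true(m$converged)
})

test_that("two tones are separated and each mode owns its tone", {
  t <- seq_len(1024)
  s <- eeg_signal(cos(2 * pi * 0.05 * t) + cos(2 * pi * 0.25 * t), fs = 250)
  m <- vmd_decompose(s, vmd_config(K = 2, alpha = 2000, gamma = 0,
                                   init = c(0.125, 0.375)))
  expect_lt(abs(m$center_freqs[1] - 0.05), 0.005)
  expect_lt(abs(m$center_freqs[2] - 0.25), 0.005)
  # per-tone band-pass energy: each mode's energy concentrates on its tone
  expect_gt(power_fraction(m$modes[, 1], 0.03, 0.07), 0.9)
  expect_gt(power_fraction(m$modes[, 2], 0.23, 0.27), 0.9)
  expect_equal(periodogram_peak(m$modes[, 1]), 0.05, tolerance = 0.005)
  expect_equal(periodogram_peak(m$modes[, 2]), 0.25, tolerance = 0.005)
  # reconstruction constraint (gamma = 0 may drop a small residual)
  r <- reconstruct(m)
  expect_lt(sum((s$samples - r$samples)^2) / sum(s$samples^2), 0.05)
})

test_that("center frequencies are returned in non-decreasing order", {
  recs <- lapply(1:3, function(sd) {
    simulate_recording(sim_config(seed = sd, duration_s = 4))
  })
  for (rec in recs) {
    m <- vmd_decompose(rec$mixture, vmd_default_config(250))
    expect_true(all(diff(m$center_freqs) >= 0))
    expect_true(all(m$center_freqs >= 0 & m$center_freqs < 0.5))
    expect_lte(m$n_iters, 500)
  }
})

test_that("decomposition is linear in the input amplitude", {
  t <- seq_len(1024)
  s <- eeg_signal(cos(2 * pi * 0.05 * t) + cos(2 * pi * 0.25 * t), 250)
  cfg <- vmd_config(K = 2, alpha = 2000, init = c(0.125, 0.375))
  m1 <- vmd_decompose(s, cfg)
  m2 <- vmd_decompose(eeg_signal(2 * s$samples, 250), cfg)
  expect_equal(m2$modes, 2 * m1$modes, tolerance = 1e-8)
  expect_equal(m2$center_freqs, m1$center_freqs, tolerance = 1e-8)
})

test_that("reconstruct obeys the summation contract", {
  m <- mode_set(list(sin(1:100), -sin(1:100)), center_freqs = c(0.1, 0.2),
                fs = 100)
  expect_equal(reconstruct(m)$samples, rep(0, 100))
  single <- mode_set(matrix(cos(1:100), ncol = 1), center_freqs = 0.3,
                     fs = 100)
  expect_equal(reconstruct(single)$samples, cos(1:100))
  expect_error(mode_set(list(1:10, 1:9), c(0.1, 0.2), 100), "same length")
})

test_that("invalid inputs and configs are rejected", {
  expect_error(eeg_signal(c(1, NA, 3), 250), "non-finite")
  expect_error(eeg_signal(1, 250), "at least 2")
  expect_error(vmd_decompose(eeg_signal(rnorm(10), 250),
                             vmd_config(K = 6)), "half the signal length")
  expect_error(vmd_config(K = 2, init = c(0.1, 0.2, 0.3)), "exactly K")
  expect_error(vmd_config(K = 2, init = c(0.1, 0.6)), "0.5")
  expect_error(vmd_config(epsilon = 0), "positive")
  expect_error(vmd_decompose(eeg_signal(rnorm(64), 250),
                             vmd_config(K = 2, init = "random")), "seed")
})

test_that("hitting the iteration cap flags non-convergence without error", {
  rec <- simulate_recording(sim_config(seed = 11, snr_db = -6,
                                       duration_s = 4))
  cfg <- vmd_config(K = 3, alpha = 1000, gamma = 1,
                    init = vmd_init_hz(c(5, 30, 100), 250), max_iters = 50)
  m <- vmd_decompose(rec$mixture, cfg)
  expect_false(m$converged)
  expect_equal(m$n_iters, 50)
})

test_that("gamma = 0 converges faster than gamma = 1 at low SNR", {
  rec <- simulate_recording(sim_config(seed = 11, snr_db = -6))
  init <- vmd_init_hz(c(5, 30, 100), 250)
  m0 <- vmd_decompose(rec$mixture, vmd_config(K = 3, alpha = 1000,
                                              gamma = 0, init = init))
  m1 <- vmd_decompose(rec$mixture, vmd_config(K = 3, alpha = 1000,
                                              gamma = 1, init = init))
  expect_true(m0$converged)
  expect_lt(m0$n_iters, m1$n_iters)
})

test_that("mode set CSV round-trips with its JSON sidecar", {
  m <- vmd_decompose(three_band_signal(512), vmd_config(K = 3, alpha = 2000))
  path <- file.path(tempdir(), "modes.csv")
  write_modeset_csv(m, path)
  m2 <- read_modeset_csv(path)
  expect_equal(m2$modes, m$modes, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$center_freqs, m$center_freqs, tolerance = 1e-12)
  expect_equal(m2$fs, m$fs)
})
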