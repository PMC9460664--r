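test_that("surrogate components are band-limited and standardized", {
  for (band in list(c(10, 50), c(0, 5), c(80, 125))) {
    comp <- make_component(band, 250, 4, seed = 41)
    expect_gt(power_fraction(comp$samples, band[1] / 250, band[2] / 250),
              0.99)
    expect_equal(mean(comp$samples), 0, tolerance = 1e-12)
    expect_equal(sd(comp$samples), 1, tolerance = 1e-12)
  }
  expect_error(make_component(c(5, 5), 250, 4, seed = 1), "increasing")
  expect_error(make_component(c(80, 200), 250, 4, seed = 1), "fs/2")
})

test_that("components are a pure function of their seed", {
  a <- make_component(c(10, 50), 250, 4, seed = 42)
  b <- make_component(c(10, 50), 250, 4, seed = 42)
  c_ <- make_component(c(10, 50), 250, 4, seed = 43)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c_$samples))
  eo1 <- make_component(c(0, 5), 250, 4, seed = 42, kind = "eog")
  eo2 <- make_component(c(0, 5), 250, 4, seed = 42, kind = "eog")
  expect_identical(eo1$samples, eo2$samples)
})

test_that("mixing hits the requested SNR exactly", {
  eeg <- make_component(c(10, 50), 250, 4, seed = 1)
  art <- make_component(c(80, 125), 250, 4, seed = 2)
  for (snr in c(0, -1, 3.5)) {
    mx <- mix_at_snr(eeg, art, snr)
    achieved <- 10 * log10(mean(eeg$samples^2) /
                             mean((mx$mixture$samples - eeg$samples)^2))
    expect_equal(achieved, snr, tolerance = 1e-6)
  }
  # snr 0: equal powers
  mx0 <- mix_at_snr(eeg, art, 0)
  expect_equal(mean(eeg$samples^2),
               mean((mx0$theta * art$samples)^2), tolerance = 1e-9)
  # doubling the artifact halves theta
  art2 <- eeg_signal(2 * art$samples, 250)
  expect_equal(mix_at_snr(eeg, art2, -1)$theta,
               mix_at_snr(eeg, art, -1)$theta / 2, tolerance = 1e-12)
})

test_that("zero artifact power is rejected", {
  eeg <- make_component(c(10, 50), 250, 4, seed = 1)
  zero <- eeg_signal(rep(0, length(eeg$samples)), 250)
  expect_error(mix_at_snr(eeg, zero, -1), "zero")
})

test_that("whole recordings are reproducible from their configuration", {
  r1 <- simulate_recording(sim_config(seed = 9, snr_db = -1))
  r2 <- simulate_recording(sim_config(seed = 9, snr_db = -1))
  expect_identical(r1$mixture$samples, r2$mixture$samples)
  expect_identical(r1$theta, r2$theta)
  expect_named(r1$artifacts, c("eog", "emg"))
  # the sweep is one documented call
  sw <- snr_sweep(seed = 3, duration_s = 4)
  expect_named(sw, c("-1.5", "-1", "-0.5", "0", "0.5", "1", "1.5"))
  sw2 <- snr_sweep(seed = 3, duration_s = 4)
  expect_identical(sw[["0"]]$mixture$samples, sw2[["0"]]$mixture$samples)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(duration_s = 1, fs = 250), "512")
  expect_error(sim_config(bands = list(eog = c(0, 5), eeg = c(10, 200),
                                       emg = c(80, 125))), "fs/2")
  # EMG band above Nyquist is clamped, not an error
  cfg <- sim_config(bands = list(eog = c(0, 5), eeg = c(10, 50),
                                 emg = c(80, 250)))
  expect_equal(cfg$bands$emg[2], 125)
})
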