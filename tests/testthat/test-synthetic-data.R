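test_that("minimum-jerk trajectory has exact endpoints and the closed-form peak velocity", {
  tr <- minimum_jerk_trajectory(90, 160, 1, 125)
  expect_equal(tr$elbow_angle_deg[1], 90)
  expect_equal(tr$elbow_angle_deg[nrow(tr)], 160)
  v <- angular_velocity(tr)
  # velocity vanishes at both ends and peaks at 15*dtheta/(8T) mid-movement
  expect_lt(abs(v$velocity_dps[1]), 0.5)
  expect_lt(abs(v$velocity_dps[nrow(v)]), 0.5)
  expect_equal(max(abs(v$velocity_dps)), 15 * 70 / 8, tolerance = 0.5 / 131.25)
  expect_equal(v$time_s[which.max(abs(v$velocity_dps))], 0.5, tolerance = 0.01)

  flat <- minimum_jerk_trajectory(120, 120, 1, 125)
  expect_true(all(flat$elbow_angle_deg == 120))
  expect_true(all(abs(angular_velocity(flat)$velocity_dps) == 0))

  expect_error(minimum_jerk_trajectory(90, 160, -1, 125), "positive")
  expect_error(minimum_jerk_trajectory(90, 160, 1, 0), "positive")
})

test_that("theoretical_msc matches its closed form and guards degenerate inputs", {
  expect_equal(theoretical_msc(c(1, 1), 1, c(1, 1)), 0.25)
  expect_equal(theoretical_msc(c(0, 1), 1, c(1, 1)), 0)
  expect_equal(theoretical_msc(c(1, 1), 1, c(0, 0)), 1)
  # equals (SNR/(1+SNR))^2 for equal channels
  snr <- 3
  expect_equal(theoretical_msc(c(1, 1), snr, c(1, 1)), (snr / (1 + snr))^2)
  expect_error(theoretical_msc(c(0, 1), 1, c(0, 1)), "zero total power")
  expect_error(theoretical_msc(c(-1, 1), 1, c(1, 1)), ">= 0")
})

test_that("band-limited source concentrates its power in the requested band", {
  n <- 2^16
  fs <- 1000
  withr::with_seed(11, {
    s <- imcoh:::band_limited_noise(n, fs, c(13, 31), 1e-3)
  })
  p <- Mod(stats::fft(s))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq > 0 & freq < fs / 2
  inband <- half & freq >= 13 & freq <= 31
  expect_gte(sum(p[inband]) / sum(p[half]), 0.95)
})

test_that("generated common-drive pairs are deterministic and match theory via a Welch oracle", {
  g1 <- generate_common_drive_emg(2^14, 1000, seed = 99)
  g2 <- generate_common_drive_emg(2^14, 1000, seed = 99)
  expect_identical(g1$trials$emg[[1]], g2$trials$emg[[1]])

  # long-run empirical MSC vs closed form, three coupling settings
  n <- 2^18
  for (case in list(list(g = c(1, 1), p = c(1e-3, 1e-3), tol = 0.05),
                    list(g = c(0.5, 1.5), p = c(2e-3, 0.5e-3), tol = 0.05))) {
    gen <- generate_common_drive_emg(n, 1000, gains = case$g, source_power = 1e-3,
                                     noise_powers = case$p, seed = 5)
    e <- gen$trials$emg[[1]]
    w <- welch_msc(e$emg1_v, e$emg2_v, 1000)
    inband <- w$freq_hz >= 16 & w$freq_hz <= 28  # interior of the 13-31 band
    expect_equal(mean(w$msc[inband]), gen$truth$theoretical_msc, tolerance = case$tol)
  }

  # no coupling: in-band MSC at the estimator bias floor only
  gen0 <- generate_common_drive_emg(n, 1000, gains = c(0, 0), seed = 5)
  e <- gen0$trials$emg[[1]]
  w <- welch_msc(e$emg1_v, e$emg2_v, 1000)
  expect_lt(mean(w$msc[w$freq_hz >= 13 & w$freq_hz <= 31]), 0.03)

  # noiseless identical-gain channels are equal and fully coherent
  gid <- generate_common_drive_emg(2^12, 1000, gains = c(1, 1), noise_powers = c(0, 0),
                                   seed = 3)
  e <- gid$trials$emg[[1]]
  expect_equal(e$emg1_v, e$emg2_v)
  expect_equal(gid$truth$theoretical_msc, 1)

  expect_error(generate_common_drive_emg(1000, 1000, band = c(100, 600)), "Nyquist|fs/2")
})

test_that("simulated sessions are reproducible with seed-invariant event times", {
  cfg <- synth_config(n_trials = 3, seed = 21)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$recording$emg, s2$recording$emg)
  expect_identical(s1$mvc, s2$mvc)

  cfg2 <- synth_config(n_trials = 3, seed = 22)
  s3 <- simulate_session(cfg2)
  expect_identical(s1$truth$events, s3$truth$events)       # same timeline
  expect_false(identical(s1$recording$emg$emg_br_v, s3$recording$emg$emg_br_v))

  # exactly one MVC trial carries the maximal torque
  plateau_torque <- purrr::map_dbl(s1$mvc$data, function(d) {
    mean(d$torque_nm[d$time_s >= 1 & d$time_s <= 4])
  })
  expect_equal(sum(plateau_torque > max(plateau_torque) - 2), 1)
  expect_equal(which.max(plateau_torque), s1$truth$mvc_max_trial)
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(n_trials = 1), ">= 2")
  expect_error(synth_config(drive_band = c(31, 13)), "increasing")
  expect_error(synth_config(drive_band = c(100, 600)), "fs_emg/2")
  expect_error(synth_config(source_power = -1), ">= 0")
  expect_error(synth_config(rest_range = c(15, 8)), "interval")
})
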