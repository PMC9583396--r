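make_ts <- function(x, fs = 1000) tibble::tibble(time_s = seq_along(x) / fs, v = x)

test_that("zero-lag band-stop passes DC exactly and suppresses the stop-band tone", {
  fs <- 1000
  const <- make_ts(rep(2.5, 4000), fs)
  out <- zero_lag_butterworth(const, "v", kind = "stop", cutoffs = c(49, 51))
  expect_lt(max(abs(out$v - 2.5)) / 2.5, 1e-6)

  t <- seq(1 / fs, 6, by = 1 / fs)
  tone <- tibble::tibble(time_s = t, v = sin(2 * pi * 50 * t))
  out <- zero_lag_butterworth(tone, "v", kind = "stop", cutoffs = c(49, 51))
  mid <- out$v[t > 2 & t < 4]
  expect_lt(max(abs(mid)), 0.01)

  expect_error(zero_lag_butterworth(tone, "v", kind = "low", cutoffs = 600), "Nyquist")
  expect_error(zero_lag_butterworth(tone, "v", kind = "band", cutoffs = c(51, 49)),
               "increasing")
})

test_that("zero-phase filtering leaves a symmetric pulse's peak in place and has zero lag", {
  fs <- 125
  t <- seq(1 / fs, 20, by = 1 / fs)
  pulse <- tibble::tibble(time_s = t, v = exp(-(t - 10)^2 / (2 * 0.5^2)))
  out <- zero_lag_butterworth(pulse, "v", kind = "low", cutoffs = 6)
  expect_equal(out$time_s[which.max(out$v)], 10, tolerance = 1 / fs / 10)

  # cross-correlation between band-limited noise and its filtered copy peaks at lag 0
  withr::with_seed(4, x <- rnorm(4000))
  xf <- zero_lag_butterworth(make_ts(x), "v", kind = "band", cutoffs = c(5, 40))
  xff <- zero_lag_butterworth(xf, "v", kind = "low", cutoffs = 60)
  cc <- stats::ccf(xf$v, xff$v, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("EMG preprocessing keeps the passband and rejects out-of-band power", {
  fs <- 1000
  withr::with_seed(9, x <- rnorm(2^15))
  out <- preprocess_emg(make_ts(x, fs), "v")
  p_in <- Mod(stats::fft(x))^2
  p_out <- Mod(stats::fft(out$v))^2
  freq <- (seq_along(x) - 1) * fs / length(x)
  hi <- freq > 120 & freq < fs / 2
  expect_gte(10 * log10(sum(p_in[hi]) / sum(p_out[hi])), 20)

  t <- seq(1 / fs, 4, by = 1 / fs)
  tone <- tibble::tibble(time_s = t, v = sin(2 * pi * 20 * t))
  out <- preprocess_emg(tone, "v")
  expect_equal(max(abs(out$v[t > 1 & t < 3])), 1, tolerance = 0.05)

  zero <- make_ts(rep(0, 3000), fs)
  expect_equal(preprocess_emg(zero, "v")$v, rep(0, 3000))
  expect_error(preprocess_emg(make_ts(rnorm(500), 150), "v"), "200 Hz")
})

test_that("angular velocity is exact for ramps and recovers the minimum-jerk peak", {
  fs <- 125
  t <- seq(0, 2, by = 1 / fs)
  ramp <- tibble::tibble(time_s = t, elbow_angle_deg = 90 + 10 * t)
  v <- angular_velocity(ramp)
  expect_equal(v$velocity_dps[2:(length(t) - 1)], rep(10, length(t) - 2))

  const <- tibble::tibble(time_s = t, elbow_angle_deg = rep(120, length(t)))
  expect_true(all(angular_velocity(const)$velocity_dps == 0))

  mj <- minimum_jerk_trajectory(90, 160, 1, fs)
  vmax <- max(abs(angular_velocity(mj)$velocity_dps))
  expect_equal(vmax, 131.25, tolerance = 0.5 / 131.25)

  expect_error(angular_velocity(ramp[1:2, ]), "3 samples")
})

test_that("movement bounds recover analytic threshold crossings on noiseless movements", {
  fs <- 125
  # two separated minimum-jerk extensions embedded in rest
  mj <- minimum_jerk_trajectory(90, 160, 1, fs)$elbow_angle_deg
  angle <- c(rep(90, 5 * fs), mj, rep(160, 5 * fs), rev(mj), rep(90, 5 * fs))
  t <- seq_along(angle) / fs
  v <- angular_velocity(tibble::tibble(time_s = t, elbow_angle_deg = angle))
  b <- detect_movement_bounds(v)
  expect_equal(nrow(b), 2)
  expect_true(all(diff(b$onset_s) > 0))
  expect_true(all(b$onset_s < b$peak_velocity_s & b$peak_velocity_s < b$offset_s))

  # analytic 0.01 deg/s crossing of the first movement, which starts at
  # sample index 5*fs + 1, i.e. t = (5*fs + 1)/fs on this time grid
  t_start <- (5 * fs + 1) / fs
  tau_cross <- imcoh:::min_jerk_threshold_time(70, 1, 0.01)
  expect_lt(abs(b$onset_s[1] - (t_start + tau_cross)), 0.010)
  expect_lt(abs(b$offset_s[1] - (t_start + 1 - tau_cross)), 0.010)
  expect_equal(b$peak_velocity_dps[1], 131.25, tolerance = 0.5 / 131.25)

  # direction filter separates extension from the return movement
  expect_equal(nrow(detect_movement_bounds(v, direction = "positive")), 1)
  expect_equal(detect_movement_bounds(v, direction = "positive")$peak_velocity_dps > 0, TRUE)

  none <- detect_movement_bounds(tibble::tibble(time_s = t, velocity_dps = rep(0, length(t))))
  expect_equal(nrow(none), 0)
  expect_error(detect_movement_bounds(tibble::tibble(time_s = t[1:3], velocity_dps = c(1, NA, 2))),
               "finite")
})

test_that("re-detecting bounds on a trial's own velocity segment is idempotent", {
  fs <- 125
  mj <- minimum_jerk_trajectory(90, 160, 1, fs)$elbow_angle_deg
  angle <- c(rep(90, 6 * fs), mj, rep(160, 6 * fs))
  t <- seq_along(angle) / fs
  v <- angular_velocity(tibble::tibble(time_s = t, elbow_angle_deg = angle))
  b <- detect_movement_bounds(v)
  seg <- v[v$time_s >= b$onset_s - 2 & v$time_s <= b$offset_s + 2, ]
  b2 <- detect_movement_bounds(seg)
  expect_lt(abs(b2$onset_s - b$onset_s), 1 / fs + 1e-9)
  expect_lt(abs(b2$offset_s - b$offset_s), 1 / fs + 1e-9)
})

test_that("trial extraction pads movements and drops those without room", {
  cfg <- synth_config(n_trials = 3, seed = 5)
  ses <- simulate_session(cfg)
  kin <- zero_lag_butterworth(ses$recording$kin, "elbow_angle_deg", "low", 6)
  b <- detect_movement_bounds(angular_velocity(kin), direction = "positive")
  expect_equal(nrow(b), 3)
  trials <- extract_trials(ses$recording, b, pad = 3)
  expect_equal(nrow(trials), 3)
  durs <- purrr::map_dbl(trials$emg, ~ diff(range(.x$time_s)))
  expect_equal(durs, b$duration_s + 6, tolerance = 2e-3)

  # a movement at the very start of the recording is dropped with a warning
  b_bad <- dplyr::bind_rows(dplyr::mutate(b[1, ], onset_s = 0.5, offset_s = 1.5,
                                          peak_velocity_s = 1), b)
  expect_warning(tr2 <- extract_trials(ses$recording, b_bad, pad = 3), "dropping 1")
  expect_equal(nrow(tr2), 3)
})
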