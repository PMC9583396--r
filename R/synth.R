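# Synthetic session generator: minimum-jerk elbow extensions, paired EMG
# sharing a band-limited common drive with known theoretical coherence, and
# MVC reference contractions. Everything downstream can be verified against
# the planted ground truth.

#' Synthetic-session configuration
#'
#' Collects every parameter of the synthetic recording. The defaults mirror
#' a typical clinical elbow-extension protocol: 20 extension movements per
#' limb, kinematics at 125 Hz and EMG at 1000 Hz, randomized 8-15 s rests
#' between movements, and a beta-band (13-31 Hz) common drive shared by the
#' muscles.
#'
#' `source_power` and `noise_powers` are power spectral density levels
#' (V^2/Hz): the common drive is band-limited Gaussian noise with in-band
#' PSD `source_power`, and each muscle's independent noise is broadband
#' (3-100 Hz, the retained surface-EMG band) with PSD `noise_powers[i]`.
#' With channel `i` built as `a_i * s + n_i`, the in-band magnitude-squared
#' coherence of a pair is then the closed form of [theoretical_msc()].
#'
#' @param n_trials Number of extension movements (>= 2; default 20).
#' @param fs_emg,fs_kin EMG and kinematic sampling rates, Hz.
#' @param movement_duration Extension duration, s.
#' @param angle_start,angle_end Elbow angle at movement start/end, degrees.
#' @param rest_range Uniform range of the rest period between movements, s.
#' @param coupling_gains Named dimensionless coupling gains `a_i >= 0` of
#'   the common drive into TB, BB, BR.
#' @param drive_band Frequency interval of the common drive, Hz.
#' @param source_power In-band PSD of the common drive, V^2/Hz.
#' @param noise_powers Named per-muscle broadband-noise PSD levels, V^2/Hz.
#' @param emg_band Band of the broadband muscle noise, Hz.
#' @param cocontraction_ratio Planted flexor (BB, BR) RMS during each
#'   extension as a fraction of the MVC reference RMS.
#' @param mvc_rms Flexor RMS (V) on the plateau of the maximal MVC trial.
#' @param agonist_burst_gain Multiplicative TB amplitude burst during each
#'   extension (scale factors do not affect coherence).
#' @param movement_amplitude_cv Log-normal coefficient of variation of the
#'   planted flexor amplitude across movements (0 = none; movement-to-
#'   movement amplitude variability is not constrained by the protocol, so
#'   it is exposed rather than fixed).
#' @param angle_noise_sd Additive white noise on the recorded angle,
#'   degrees (0 = noiseless optical capture).
#' @param seed Integer seed for all stochastic content (noise draws).
#' @param timeline_seed Seed of the separate stream that draws rest
#'   durations and the maximal-MVC trial, so that event *times* are
#'   identical across `seed`s and only the noise changes.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_trials = 20, fs_emg = 1000, fs_kin = 125,
                         movement_duration = 1, angle_start = 90, angle_end = 160,
                         rest_range = c(8, 15),
                         coupling_gains = c(tb = 1, bb = 1, br = 1),
                         drive_band = c(13, 31),
                         source_power = 1e-3,
                         noise_powers = c(tb = 1e-3, bb = 1e-3, br = 1e-3),
                         emg_band = c(3, 100),
                         cocontraction_ratio = 0.30,
                         mvc_rms = 1,
                         agonist_burst_gain = 2,
                         movement_amplitude_cv = 0,
                         angle_noise_sd = 0,
                         seed = 1L, timeline_seed = 1758L) {
  cfg <- as.list(environment())
  if (n_trials < 2) abort("n_trials must be >= 2")
  if (fs_emg <= 0 || fs_kin <= 0 || movement_duration <= 0) abort("rates and durations must be positive")
  if (length(rest_range) != 2 || any(rest_range < 0) || rest_range[1] > rest_range[2]) {
    abort("rest_range must be an increasing non-negative interval")
  }
  if (any(coupling_gains < 0)) abort("coupling gains must be >= 0")
  if (length(drive_band) != 2 || drive_band[1] <= 0 || drive_band[2] >= fs_emg / 2 ||
      drive_band[1] >= drive_band[2]) {
    abort("drive_band must be an increasing interval inside (0, fs_emg/2)")
  }
  if (source_power < 0 || any(noise_powers < 0)) abort("powers must be >= 0")
  if (cocontraction_ratio < 0) abort("cocontraction_ratio must be >= 0")
  for (nm in c("coupling_gains", "noise_powers")) {
    if (!all(c("tb", "bb", "br") %in% names(cfg[[nm]]))) {
      abort(sprintf("%s must be named with tb, bb, br", nm))
    }
  }
  structure(cfg, class = "synth_config")
}

#' Minimum-jerk angle trajectory
#'
#' The smoothest point-to-point movement model commonly used for reaching:
#' theta(t) = theta0 + dtheta (10 tau^3 - 15 tau^4 + 6 tau^5), tau = t/T.
#' Velocity and acceleration vanish at both ends and peak angular velocity
#' is 15 dtheta / (8 T) at mid-movement.
#'
#' @param theta0,theta1 Start and end angle, degrees.
#' @param duration Movement duration T, s.
#' @param fs Sampling rate, Hz.
#' @return Tibble with `time_s` (0..T inclusive) and `elbow_angle_deg`.
#' @export
minimum_jerk_trajectory <- function(theta0, theta1, duration, fs) {
  if (duration <= 0 || fs <= 0) abort("duration and fs must be positive")
  n <- floor(duration * fs)
  t <- seq(0, n) / fs
  tau <- pmin(t / duration, 1)
  th <- theta0 + (theta1 - theta0) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  tibble(time_s = t, elbow_angle_deg = th)
}

# time (s from movement start) at which min-jerk |velocity| crosses `thr`
min_jerk_threshold_time <- function(dtheta, duration, thr = 0.01) {
  vmax <- 15 * abs(dtheta) / (8 * duration)
  if (thr >= vmax) return(duration / 2)
  f <- function(tau) abs(dtheta) * 30 * tau^2 * (1 - tau)^2 / duration - thr
  stats::uniroot(f, c(1e-12, 0.5), tol = 1e-12)$root * duration
}

# effective bandwidth int |H(f)|^4 df of the zero-lag band-pass used to
# shape noise (forward-backward 4th-order Butterworth)
zero_lag_bandwidth <- function(band, fs, order = 4, n = 4096) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  fr <- signal::freqz(bf$b, bf$a, n = n, Fs = fs)
  sum(Mod(fr$h)^4) * (fs / 2) / n
}

# band-limited Gaussian noise with in-band PSD `psd` (V^2/Hz); uses the
# same zero-lag 4th-order band-pass as the preprocessing stage, then
# rescales to the exact power implied by the filter's effective bandwidth
band_limited_noise <- function(n, fs, band, psd) {
  if (psd == 0) return(numeric(n))
  w <- stats::rnorm(n, sd = sqrt(psd * fs / 2))
  x <- tibble(time_s = seq_len(n) / fs, v = w)
  x <- zero_lag_butterworth(x, "v", kind = "band", cutoffs = band, fs = fs)$v
  target_var <- psd * zero_lag_bandwidth(band, fs)
  x * sqrt(target_var / stats::var(x))
}

#' Theoretical in-band coherence of a planted common drive
#'
#' For paired signals `x_i = a_i s + n_i` with a shared band-limited source
#' of in-band PSD `Ps` and independent noises of PSD `P1`, `P2`, the
#' magnitude-squared coherence at in-band frequencies is
#' `(a1 a2 Ps)^2 / ((a1^2 Ps + P1) (a2^2 Ps + P2))`.
#'
#' @param gains Length-2 coupling gains `(a1, a2)`.
#' @param source_power Source in-band PSD `Ps` (>= 0).
#' @param noise_powers Length-2 noise PSD levels `(P1, P2)`.
#' @return Coherence value in `[0, 1]`.
#' @examples
#' theoretical_msc(c(1, 1), 1, c(1, 1))  # 0.25: (SNR/(1+SNR))^2 at SNR = 1
#' @export
theoretical_msc <- function(gains, source_power, noise_powers) {
  stopifnot(length(gains) == 2, length(noise_powers) == 2)
  if (any(gains < 0) || source_power < 0 || any(noise_powers < 0)) {
    abort("gains and powers must be >= 0")
  }
  den1 <- gains[1]^2 * source_power + noise_powers[1]
  den2 <- gains[2]^2 * source_power + noise_powers[2]
  if (den1 <= 0 || den2 <= 0) abort("undefined result: a channel has zero total power")
  unname(min(1, (gains[1] * gains[2] * source_power)^2 / (den1 * den2)))
}

#' Generate paired EMG trials sharing a band-limited common drive
#'
#' Builds `n_trials` independent trial segments of two channels
#' `x_i = a_i s + n_i`, where `s` is band-limited Gaussian noise (the
#' common drive, in-band PSD `source_power`) and `n_i` is independent
#' broadband (3-100 Hz) Gaussian noise of PSD `noise_powers[i]`. The output
#' has the same nested shape as [extract_trials()], with nominal movement
#' bounds placed at the pads, so it feeds directly into
#' [trial_averaged_spectra()] and [wavelet_coherence()].
#'
#' @param n_samples Samples per trial in the analysis region (between pads).
#' @param fs Sampling rate, Hz.
#' @param gains Length-2 coupling gains.
#' @param band Drive band, Hz (inside the Nyquist range).
#' @param source_power,noise_powers PSD levels, V^2/Hz (see [synth_config()]).
#' @param n_trials Number of independent trials.
#' @param pad Pad duration on each side, s (absorbs wavelet edge effects).
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @return List with `trials` (nested tibble with channels `emg1_v`,
#'   `emg2_v`) and `truth` (the [theoretical_msc()] of the pair).
#' @export
generate_common_drive_emg <- function(n_samples, fs, gains = c(1, 1), band = c(13, 31),
                                      source_power = 1e-3, noise_powers = c(1e-3, 1e-3),
                                      n_trials = 1, pad = 0, seed = 1L) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    abort("band must be an increasing interval inside (0, fs/2)")
  }
  if (any(gains < 0) || source_power < 0 || any(noise_powers < 0)) abort("powers must be >= 0")
  npad <- round(pad * fs)
  ntot <- n_samples + 2 * npad
  trials <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(n_trials), function(i) {
      s <- band_limited_noise(ntot, fs, band, source_power)
      e1 <- gains[1] * s + band_limited_noise(ntot, fs, c(3, 100), noise_powers[1])
      e2 <- gains[2] * s + band_limited_noise(ntot, fs, c(3, 100), noise_powers[2])
      tibble(time_s = seq_len(ntot) / fs, emg1_v = e1, emg2_v = e2)
    })
  })
  dur <- n_samples / fs
  trials_tbl <- tibble(
    movement = seq_len(n_trials),
    onset_s = purrr::map_dbl(trials, ~ .x$time_s[npad + 1]),
    offset_s = purrr::map_dbl(trials, ~ .x$time_s[npad + n_samples]),
    peak_velocity_s = purrr::map_dbl(trials, ~ .x$time_s[npad + n_samples]),
    pad_s = pad,
    emg = trials)
  msc <- tryCatch(theoretical_msc(gains, source_power, noise_powers),
                  error = function(e) NA_real_)
  list(trials = trials_tbl, truth = list(theoretical_msc = msc, band = band))
}

#' Simulate a full recording session
#'
#' Generates one limb's session: a continuous elbow-angle series built from
#' minimum-jerk extensions (each followed, after a hold, by a slower return
#' flexion, as in an extension/flexion protocol where only extensions are
#' analyzed), continuous three-muscle EMG carrying the common drive, and
#' three 5 s MVC trials with a torque channel of which exactly one has
#' maximal torque. During each extension the flexor (BB, BR) samples are
#' rescaled so that their RMS over the movement equals
#' `cocontraction_ratio * mvc_rms` exactly; constant per-window scaling
#' leaves coherence untouched.
#'
#' @param config A [synth_config()].
#' @param subject,group,limb Metadata copied into the recording.
#' @return List with `recording` ([emg_recording()]), `mvc` (nested tibble:
#'   `trial`, `data` with `time_s`, `emg_bb_v`, `emg_br_v`, `torque_nm`),
#'   and `truth` (events table with analytic onset/offset/peak-velocity
#'   times, per-pair theoretical coherence, the planted co-contraction
#'   ratio and the maximal-torque trial id).
#' @export
simulate_session <- function(config = synth_config(), subject = "S1",
                             group = "control", limb = "dominant") {
  if (!inherits(config, "synth_config")) abort("`config` must come from synth_config()")
  cf <- config
  T_ext <- cf$movement_duration
  T_flex <- 2 * T_ext

  # --- timeline (independent RNG stream: identical across noise seeds);
  # each trial: rest -> extension -> rest extended (next sound) -> flexion
  tl <- withr::with_seed(as.integer(cf$timeline_seed), {
    rests <- matrix(stats::runif(2 * cf$n_trials, cf$rest_range[1], cf$rest_range[2]),
                    ncol = 2)
    list(rests = rests, mvc_max = sample.int(3, 1))
  })
  ext_start <- flex_start <- numeric(cf$n_trials)
  t_cur <- 0
  for (i in seq_len(cf$n_trials)) {
    t_cur <- t_cur + tl$rests[i, 1]
    ext_start[i] <- t_cur
    t_cur <- t_cur + T_ext + tl$rests[i, 2]
    flex_start[i] <- t_cur
    t_cur <- t_cur + T_flex
  }
  total <- t_cur + 5

  # --- kinematics
  nk <- floor(total * cf$fs_kin)
  tk <- seq(0, nk - 1) / cf$fs_kin
  angle <- rep(cf$angle_start, nk)
  ext <- minimum_jerk_trajectory(cf$angle_start, cf$angle_end, T_ext, cf$fs_kin)
  flex <- minimum_jerk_trajectory(cf$angle_end, cf$angle_start, T_flex, cf$fs_kin)
  for (i in seq_len(cf$n_trials)) {
    i0 <- round(ext_start[i] * cf$fs_kin)
    angle[(i0 + 1):nk] <- cf$angle_end
    angle[i0 + seq_len(nrow(ext))] <- ext$elbow_angle_deg
    j0 <- round(flex_start[i] * cf$fs_kin)
    angle[(j0 + 1):nk] <- cf$angle_start
    angle[j0 + seq_len(nrow(flex))] <- flex$elbow_angle_deg
  }

  # --- truth event times (analytic 0.01 deg/s crossings of the extension)
  dth <- cf$angle_end - cf$angle_start
  t_thr <- min_jerk_threshold_time(dth, T_ext, 0.01)
  events <- tibble(
    movement = seq_len(cf$n_trials),
    onset_s = ext_start + t_thr,
    peak_velocity_s = ext_start + T_ext / 2,
    offset_s = ext_start + T_ext - t_thr)

  # --- EMG + MVC (noise stream)
  ne <- floor(total * cf$fs_emg)
  te <- seq(0, ne - 1) / cf$fs_emg
  sim <- withr::with_seed(as.integer(cf$seed), {
    if (cf$angle_noise_sd > 0) {
      angle <- angle + stats::rnorm(nk, sd = cf$angle_noise_sd)
    }
    s <- band_limited_noise(ne, cf$fs_emg, cf$drive_band, cf$source_power)
    ch <- lapply(c(tb = "tb", bb = "bb", br = "br"), function(m) {
      cf$coupling_gains[[m]] * s +
        band_limited_noise(ne, cf$fs_emg, cf$emg_band, cf$noise_powers[[m]])
    })
    amp <- exp(stats::rnorm(cf$n_trials, 0, cf$movement_amplitude_cv))
    # scaling window extends 0.3 s beyond the movement so that detected
    # bounds (smoothed by the 6 Hz kinematic filter) stay inside it
    margin <- 0.3
    for (i in seq_len(cf$n_trials)) {
      idx <- which(te >= events$onset_s[i] - margin & te <= events$offset_s[i] + margin)
      core <- which(te >= events$onset_s[i] & te <= events$offset_s[i])
      for (m in c("bb", "br")) {
        target <- cf$cocontraction_ratio * cf$mvc_rms * amp[i]
        cur <- sqrt(mean(ch[[m]][core]^2))
        if (cur > 0) ch[[m]][idx] <- ch[[m]][idx] * (target / cur)
      }
      ch$tb[idx] <- ch$tb[idx] * cf$agonist_burst_gain
    }
    # MVC trials: 1 s ramps, 3 s plateau; the designated trial +10% torque
    nm <- 5 * cf$fs_emg
    tm <- seq(0, nm - 1) / cf$fs_emg
    shape <- pmin(1, pmin(tm, 5 - tm))
    plateau <- tm >= 1 & tm <= 4
    mvc <- purrr::map(1:3, function(k) {
      trq0 <- if (k == tl$mvc_max) 44 else 40
      torque <- trq0 * shape + stats::rnorm(nm, sd = 0.2)
      emg <- lapply(c(bb = "bb", br = "br"), function(m) {
        e <- band_limited_noise(nm, cf$fs_emg, cf$emg_band, cf$noise_powers[[m]]) * shape
        target <- cf$mvc_rms * trq0 / 44
        e * (target / sqrt(mean(e[plateau]^2)))
      })
      tibble(time_s = tm, emg_bb_v = emg$bb, emg_br_v = emg$br, torque_nm = torque)
    })
    list(ch = ch, mvc = mvc, angle = angle)
  })

  recording <- emg_recording(
    emg = tibble(time_s = te, emg_tb_v = sim$ch$tb, emg_bb_v = sim$ch$bb,
                 emg_br_v = sim$ch$br),
    kin = tibble(time_s = tk, elbow_angle_deg = sim$angle),
    subject = subject, group = group, limb = limb)

  pair_msc <- function(m1, m2) {
    theoretical_msc(c(cf$coupling_gains[[m1]], cf$coupling_gains[[m2]]),
                    cf$source_power,
                    c(cf$noise_powers[[m1]], cf$noise_powers[[m2]]))
  }
  truth <- list(
    events = events,
    msc = tibble(pair = c("tb_br", "bb_br", "tb_bb"),
                 theoretical_msc = c(pair_msc("tb", "br"), pair_msc("bb", "br"),
                                     pair_msc("tb", "bb"))),
    cocontraction_ratio = cf$cocontraction_ratio,
    mvc_max_trial = tl$mvc_max,
    config = cf)

  list(recording = recording,
       mvc = tibble(trial = 1:3, data = sim$mvc),
       truth = truth)
}
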