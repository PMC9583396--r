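# Independent oracles used to cross-check the package implementation.
# These deliberately use different mechanisms from the package code.

# Welch-style magnitude-squared coherence from non-overlapping segments
# (direct periodogram averaging; no wavelets).
welch_msc <- function(x, y, fs, seg_len = 2048) {
  nseg <- floor(length(x) / seg_len)
  stopifnot(nseg >= 2)
  sxx <- syy <- numeric(seg_len)
  sxy <- complex(real = numeric(seg_len))
  for (k in seq_len(nseg)) {
    i <- ((k - 1) * seg_len + 1):(k * seg_len)
    X <- stats::fft(x[i])
    Y <- stats::fft(y[i])
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  freq <- (seq_len(seg_len) - 1) * fs / seg_len
  keep <- freq > 0 & freq < fs / 2
  data.frame(freq_hz = freq[keep],
             msc = (Mod(sxy)^2 / (sxx * syy))[keep])
}

# Direct (O(n*m)) discrete-convolution Morlet CWT with the kernel truncated
# at +/- 6 Gaussian widths; the package computes the same transform by FFT.
brute_cwt <- function(x, fs, freq_hz, w0 = 10) {
  n <- length(x)
  dt <- 1 / fs
  out <- matrix(0 + 0i, length(freq_hz), n)
  for (j in seq_along(freq_hz)) {
    s <- (w0 + sqrt(2 + w0^2)) / (4 * pi * freq_hz[j])
    L <- floor(6 * s * fs)
    tt <- (-L:L) * dt
    psi <- pi^(-0.25) * sqrt(dt / s) * exp(1i * w0 * tt / s) * exp(-tt^2 / (2 * s^2))
    for (i in seq_len(n)) {
      m <- max(1, i - L):min(n, i + L)
      out[j, i] <- sum(x[m] * psi[(i - m) + L + 1])
    }
  }
  out
}

# trial table (the shape produced by extract_trials / the generator) from a
# list of per-trial two-channel matrices, pad-free, aligned at the segment end
make_trial_table <- function(xs, ys, fs) {
  n <- length(xs[[1]])
  tibble::tibble(
    movement = seq_along(xs),
    onset_s = 1 / fs,
    offset_s = n / fs,
    peak_velocity_s = n / fs,
    pad_s = 0,
    emg = purrr::map2(xs, ys, function(x, y) {
      tibble::tibble(time_s = seq_len(n) / fs, emg1_v = x, emg2_v = y)
    }))
}

# small frequency grid with a given spacing (keeps delta_f consistent)
toy_grid <- function(freqs, delta_f = diff(freqs[1:2])) {
  structure(list(freq_hz = freqs, delta_f = delta_f), class = "freq_grid")
}

# balanced null/shifted metrics table for ANCOVA calibration simulations
null_metrics <- function(n_per_group, seed, limb_shift = 0) {
  withr::with_seed(seed, {
    subj <- sprintf("s%02d", seq_len(2 * n_per_group))
    limb_subj <- rep(c("paretic", "dominant"), each = n_per_group)
    shifted <- limb_shift * rep(limb_subj == "paretic", each = 2)
    base <- tibble::tibble(
      subject = rep(subj, each = 2),
      limb = rep(limb_subj, each = 2),
      pair = rep(c("bb_br", "tb_br"), 2 * n_per_group),
      mean_angle_deg = rnorm(4 * n_per_group, 112, 4),
      mean_velocity_dps = rnorm(4 * n_per_group, 110, 15),
      age = rep(round(runif(2 * n_per_group, 40, 75)), each = 2),
      cocontraction_pct = rep(rlnorm(2 * n_per_group, 3, 0.4), each = 2),
      imc_volume = rlnorm(4 * n_per_group, 0, 0.5) + shifted)
  })
  base
}
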