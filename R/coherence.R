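# Trial-averaged wavelet spectra, magnitude-squared intermuscular
# coherence, significance masking and the band-volume statistic.

# per-trial cropped CWTs of two channels, aligned on peak velocity.
# Returns list(W1, W2: lists of freq x time complex matrices on the common
# relative-time grid; rel_idx: sample offsets re peak velocity; fs)
aligned_trial_cwts <- function(trials, channels, grid, wavenumber) {
  K <- nrow(trials)
  if (K < 2) abort("need at least 2 trials (single-trial coherence is identically 1)")
  fs <- ts_fs(trials$emg[[1]]$time_s)
  idx <- purrr::pmap(list(trials$emg, trials$onset_s, trials$offset_s,
                          trials$peak_velocity_s),
                     function(e, on, off, pv) {
                       t <- e$time_s
                       c(on = nearest_index(on, t), off = nearest_index(off, t),
                         pv = nearest_index(pv, t))
                     })
  lo <- max(purrr::map_dbl(idx, ~ .x["on"] - .x["pv"]))
  hi <- min(purrr::map_dbl(idx, ~ .x["off"] - .x["pv"]))
  if (hi <= lo) abort("trials share no common aligned time window")
  rel <- seq(lo, hi)
  cwt_crop <- function(e, ch, ix) {
    W <- morlet_cwt(e, grid, wavenumber, col = ch)
    W$values[, ix["pv"] + rel, drop = FALSE]
  }
  W1 <- purrr::map2(trials$emg, idx, ~ cwt_crop(.x, channels[1], .y))
  W2 <- purrr::map2(trials$emg, idx, ~ cwt_crop(.x, channels[2], .y))
  list(W1 = W1, W2 = W2, rel_idx = rel, fs = fs, K = K)
}

#' Trial-averaged wavelet auto- and cross-spectra
#'
#' Computes the Morlet CWT of two EMG channels for every trial, crops the
#' pads (keeping `[onset, offset]`), aligns trials at their peak-velocity
#' time, truncates to the time window common to all trials, and averages:
#' auto-spectra as mean |W|^2 and the cross-spectrum as mean W1 conj(W2).
#'
#' @param trials Nested trial table ([extract_trials()] or
#'   [generate_common_drive_emg()]).
#' @param channels Length-2 character: the two EMG columns, e.g.
#'   `c("emg_bb_v", "emg_br_v")`.
#' @param grid [build_frequency_grid()].
#' @param wavenumber Morlet omega0.
#' @return List with `auto1`, `auto2`, `cross` (`tf_map`s on the aligned
#'   time grid, seconds relative to peak velocity) and `K` (trial count).
#' @export
trial_averaged_spectra <- function(trials, channels, grid = build_frequency_grid(),
                                   wavenumber = 10) {
  a <- aligned_trial_cwts(trials, channels, grid, wavenumber)
  nt <- length(a$rel_idx)
  nf <- length(grid$freq_hz)
  auto1 <- auto2 <- matrix(0, nf, nt)
  cross <- matrix(0 + 0i, nf, nt)
  for (k in seq_len(a$K)) {
    auto1 <- auto1 + Mod(a$W1[[k]])^2
    auto2 <- auto2 + Mod(a$W2[[k]])^2
    cross <- cross + a$W1[[k]] * Conj(a$W2[[k]])
  }
  time_rel <- a$rel_idx / a$fs
  list(auto1 = tf_map(auto1 / a$K, grid, time_rel, "power", a$K),
       auto2 = tf_map(auto2 / a$K, grid, time_rel, "power", a$K),
       cross = tf_map(cross / a$K, grid, time_rel, "cross", a$K),
       K = a$K)
}

#' Magnitude-squared coherence from averaged spectra
#'
#' `msc = |cross|^2 / (auto1 * auto2)`, elementwise, clipped to `[0, 1]`
#' against rounding. Cells with a zero auto-spectrum are set to `NA` with a
#' warning.
#'
#' @param cross,auto1,auto2 `tf_map`s from [trial_averaged_spectra()].
#' @return A `tf_map` of kind `"msc"` with values in `[0, 1]`.
#' @export
magnitude_squared_coherence <- function(cross, auto1, auto2) {
  if (!identical(dim(cross$values), dim(auto1$values)) ||
      !identical(dim(cross$values), dim(auto2$values))) {
    abort("cross and auto spectra must have identical shapes")
  }
  den <- auto1$values * auto2$values
  bad <- den <= 0
  if (any(bad)) {
    warn(sprintf("%d cell(s) with zero auto-spectrum set to NA", sum(bad)))
    den[bad] <- NA_real_
  }
  msc <- Mod(cross$values)^2 / den
  msc <- pmin(pmax(msc, 0), 1)
  m <- tf_map(msc, cross, cross$time_s, "msc", cross$n_trials)
  m
}

#' Analytic significance threshold and mask for trial-averaged coherence
#'
#' Under independence, coherence averaged over `K` trials exceeds
#' `1 - alpha^(1/(K-1))` with probability `alpha` (the classical threshold
#' for magnitude-squared coherence estimated from K independent segments).
#' A cell is flagged significant when its coherence exceeds the threshold.
#' A precomputed (e.g. surrogate-based) threshold can be supplied instead.
#'
#' @param msc A `tf_map` of kind `"msc"`.
#' @param K Number of trials averaged (>= 2).
#' @param alpha Significance level in (0, 1).
#' @param threshold Optional scalar overriding the analytic rule.
#' @return A logical `tf_map` of kind `"mask"` with attribute `threshold`.
#' @export
coherence_significance_mask <- function(msc, K, alpha = 0.05, threshold = NULL) {
  if (K < 2) abort("K must be >= 2")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  thr <- threshold %||% (1 - alpha^(1 / (K - 1)))
  m <- tf_map(!is.na(msc$values) & msc$values > thr, msc, msc$time_s, "mask", K)
  attr(m, "threshold") <- thr
  m
}

#' Trial-averaged wavelet intermuscular coherence
#'
#' End-to-end coherence for one muscle pair: per-trial Morlet transforms,
#' pad cropping, peak-velocity alignment, trial averaging, coherence, and
#' significance masking (analytic rule by default; optionally a surrogate
#' threshold from trial-shuffled pairings, which destroys within-trial
#' coupling while keeping each channel's spectra).
#'
#' @inheritParams trial_averaged_spectra
#' @param pair Label for the pair (default from channel names).
#' @param params [wavelet_params()] (supplies omega0 and alpha).
#' @param significance `"analytic"` or `"surrogate"`.
#' @param n_surrogates Number of shuffled pairings for the surrogate rule.
#' @return Object of class `imc_coherence`: `msc` and `mask` (`tf_map`s),
#'   `threshold`, `K`, `pair`, the averaged spectra, and metadata on the
#'   significance rule.
#' @export
wavelet_coherence <- function(trials, channels = c("emg_bb_v", "emg_br_v"),
                              pair = NULL, params = wavelet_params(),
                              grid = NULL, significance = c("analytic", "surrogate"),
                              n_surrogates = 100) {
  significance <- match.arg(significance)
  fs <- ts_fs(trials$emg[[1]]$time_s)
  grid <- grid %||% build_frequency_grid(params, fs)
  a <- aligned_trial_cwts(trials, channels, grid, params$wavenumber)
  nf <- length(grid$freq_hz)
  nt <- length(a$rel_idx)
  avg <- function(W1, W2) {
    auto1 <- auto2 <- matrix(0, nf, nt)
    cross <- matrix(0 + 0i, nf, nt)
    for (k in seq_along(W1)) {
      auto1 <- auto1 + Mod(W1[[k]])^2
      auto2 <- auto2 + Mod(W2[[k]])^2
      cross <- cross + W1[[k]] * Conj(W2[[k]])
    }
    K <- length(W1)
    list(a1 = auto1 / K, a2 = auto2 / K, cr = cross / K)
  }
  s <- avg(a$W1, a$W2)
  time_rel <- a$rel_idx / a$fs
  auto1 <- tf_map(s$a1, grid, time_rel, "power", a$K)
  auto2 <- tf_map(s$a2, grid, time_rel, "power", a$K)
  cross <- tf_map(s$cr, grid, time_rel, "cross", a$K)
  msc <- magnitude_squared_coherence(cross, auto1, auto2)

  thr <- NULL
  if (significance == "surrogate") {
    pool <- numeric(0)
    for (b in seq_len(n_surrogates)) {
      p <- shifted_permutation(a$K, b)
      sb <- avg(a$W1, a$W2[p])
      mb <- Mod(sb$cr)^2 / (sb$a1 * sb$a2)
      smp <- if (length(mb) > 5000) sample(mb, 5000) else as.vector(mb)
      pool <- c(pool, smp)
      if (length(pool) > 5e5) pool <- sample(pool, 2.5e5)
    }
    thr <- stats::quantile(pool, 1 - params$alpha, names = FALSE)
  }
  mask <- coherence_significance_mask(msc, a$K, params$alpha, threshold = thr)

  structure(list(msc = msc, mask = mask, threshold = attr(mask, "threshold"),
                 auto1 = auto1, auto2 = auto2, cross = cross,
                 K = a$K, pair = pair %||% paste(channels, collapse = "/"),
                 params = params, significance = significance),
            class = "imc_coherence")
}

# deterministic cyclic-shift permutation (a derangement for 0 < b mod K < K)
shifted_permutation <- function(K, b) {
  s <- (b - 1L) %% (K - 1L) + 1L
  ((seq_len(K) - 1L + s) %% K) + 1L
}

#' @export
print.imc_coherence <- function(x, ...) {
  cat(sprintf("<imc_coherence> pair %s, K = %d trials\n", x$pair, x$K))
  cat(sprintf("  %d freqs x %d times; %s threshold %.4f; %.1f%% cells significant\n",
              length(x$msc$freq_hz), length(x$msc$time_s), x$significance,
              x$threshold, 100 * mean(x$mask$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.imc_coherence <- function(x, ...) {
  out <- tidy(x$msc)
  names(out)[names(out) == "value"] <- "msc"
  out$significant <- as.vector(x$mask$values)
  out
}

#' @export
glance.imc_coherence <- function(x, ...) {
  tibble(pair = x$pair, n_trials = x$K, threshold = x$threshold,
         significance = x$significance,
         frac_significant = mean(x$mask$values, na.rm = TRUE),
         mean_msc = mean(x$msc$values, na.rm = TRUE))
}

#' Significant-coherence volume in a frequency band and time window
#'
#' Integrates significant coherence over a band-by-window region anchored
#' to peak velocity: `volume = sum(msc * mask) * delta_f * delta_t` over
#' cells with frequency inside `band` and time inside `window` (units:
#' coherence x Hz x s). By convention the beta band is 13-31 Hz and the
#' window the 200 ms before peak velocity. When the trial table is
#' supplied, the mean elbow angle and mean angular velocity over the same
#' window (model covariates) are averaged across trials from each trial's
#' kinematic segment.
#'
#' @param coh An `imc_coherence` object.
#' @param trials Optional trial table with a `kin` list column (for the
#'   angle/velocity covariates).
#' @param band Frequency band, Hz.
#' @param window Time window relative to peak velocity, s.
#' @param subtract_threshold If `TRUE`, integrate `msc - threshold` over
#'   significant cells instead of raw coherence.
#' @return One-row tibble: `pair`, `imc_volume`, `n_trials`,
#'   `frac_significant` (within the region), and (with `trials`)
#'   `mean_angle_deg`, `mean_velocity_dps`.
#' @export
imc_volume <- function(coh, trials = NULL, band = c(13, 31), window = c(-0.2, 0),
                       subtract_threshold = FALSE) {
  if (!inherits(coh, "imc_coherence")) abort("`coh` must be an imc_coherence")
  if (band[1] >= band[2] || window[1] >= window[2]) {
    abort("band and window must be increasing intervals")
  }
  fi <- which(coh$msc$freq_hz >= band[1] & coh$msc$freq_hz <= band[2])
  ti <- which(coh$msc$time_s >= window[1] - 1e-9 & coh$msc$time_s <= window[2] + 1e-9)
  if (!length(fi) || !length(ti)) abort("band/window selects no time-frequency cells")
  dt <- stats::median(diff(coh$msc$time_s))
  v <- coh$msc$values[fi, ti, drop = FALSE]
  if (subtract_threshold) v <- v - coh$threshold
  m <- coh$mask$values[fi, ti, drop = FALSE]
  vol <- sum(v * m, na.rm = TRUE) * coh$msc$delta_f * dt
  out <- tibble(pair = coh$pair, imc_volume = vol, n_trials = coh$K,
                frac_significant = mean(m, na.rm = TRUE))
  if (!is.null(trials)) {
    cov <- purrr::pmap(list(trials$kin, trials$peak_velocity_s), function(k, pv) {
      vel <- angular_velocity(k)
      sel <- k$time_s - pv >= window[1] - 1e-9 & k$time_s - pv <= window[2] + 1e-9
      c(ang = mean(k$elbow_angle_deg[sel]), vel = mean(vel$velocity_dps[sel]))
    })
    out$mean_angle_deg <- mean(purrr::map_dbl(cov, "ang"))
    out$mean_velocity_dps <- mean(purrr::map_dbl(cov, "vel"))
  }
  out
}
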