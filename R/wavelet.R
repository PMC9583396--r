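# Morlet continuous wavelet transform on a linear frequency grid.
#
# The transform is computed in the frequency domain: the signal is
# zero-padded to a power of two, Fourier transformed once, multiplied by
# the analytic Morlet spectrum at every grid frequency, and inverted with
# a single batched inverse FFT. With zero padding this equals linear
# convolution with the (complex-conjugated, time-reversed) Morlet wavelet,
# which is what a direct convolution implementation computes.

#' Wavelet analysis parameters
#'
#' `nvoice` (scale resolution) and `J1` (number of scales) jointly set the
#' number of frequency bins (`nvoice * J1`); `wavenumber` is the Morlet
#' mother-wavelet parameter (omega0), which trades frequency resolution
#' against time resolution. The defaults (7, 50, 10) give 350 bins and,
#' over an EMG band around 13-31 Hz, roughly a 0.1 s by 3 Hz precision
#' cell.
#'
#' @param nvoice,J1 Positive integers; `nvoice * J1` frequency bins.
#' @param wavenumber Morlet omega0 (>= 6 for admissibility; default 10).
#' @param alpha Significance level for coherence masking (default 0.05).
#' @return List of class `wavelet_params`.
#' @export
wavelet_params <- function(nvoice = 7, J1 = 50, wavenumber = 10, alpha = 0.05) {
  if (nvoice * J1 < 1) abort("nvoice * J1 must be >= 1")
  if (wavenumber < 6) abort("wavenumber must be >= 6 (Morlet admissibility)")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  structure(list(nvoice = nvoice, J1 = J1, wavenumber = wavenumber, alpha = alpha),
            class = "wavelet_params")
}

#' Linear frequency grid for the wavelet transform
#'
#' `nvoice * J1` uniformly spaced center frequencies `j * delta_f`,
#' `j = 1..nvoice*J1`, spanning up to `f_max` (79.97 Hz by default, giving
#' a 0.23 Hz lowest bin and 0.23 Hz spacing with the default 350 bins).
#'
#' @param params [wavelet_params()].
#' @param fs Sampling rate, Hz; the grid must stay below `fs/2`.
#' @param f_max Highest center frequency, Hz.
#' @param range Optional length-2 interval: keep only bins inside it (the
#'   spacing `delta_f` is unchanged, so band volumes are identical; this
#'   only avoids computing frequencies that are never used).
#' @return List of class `freq_grid` with `freq_hz` (ascending) and
#'   `delta_f` (bin width, Hz).
#' @export
build_frequency_grid <- function(params = wavelet_params(), fs = 1000,
                                 f_max = 79.97, range = NULL) {
  nf <- params$nvoice * params$J1
  if (f_max >= fs / 2) abort("frequency grid would exceed the Nyquist frequency")
  delta_f <- f_max / nf
  freq <- seq_len(nf) * delta_f
  if (!is.null(range)) {
    freq <- freq[freq >= range[1] & freq <= range[2]]
    if (!length(freq)) abort("`range` leaves no grid frequencies")
  }
  structure(list(freq_hz = freq, delta_f = delta_f), class = "freq_grid")
}

# Morlet scale for a given center (peak-energy) frequency
morlet_scale <- function(f, w0) (w0 + sqrt(2 + w0^2)) / (4 * pi * f)

# cache of Morlet spectra keyed by (N2, dt, w0, grid)
.psi_cache <- new.env(parent = emptyenv())

morlet_spectra <- function(freq_hz, w0, n2, dt) {
  key <- rlang::hash(list(freq_hz, w0, n2, dt))
  if (!is.null(.psi_cache[[key]])) return(.psi_cache[[key]])
  k <- c(seq(0, n2 / 2), seq(-n2 / 2 + 1, -1))
  omega <- 2 * pi * k / (n2 * dt)
  psi <- matrix(0, n2, length(freq_hz))
  for (j in seq_along(freq_hz)) {
    s <- morlet_scale(freq_hz[j], w0)
    h <- numeric(n2)
    pos <- omega > 0
    h[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) * exp(-(s * omega[pos] - w0)^2 / 2)
    psi[, j] <- h
  }
  if (length(ls(.psi_cache)) > 8) rm(list = ls(.psi_cache), envir = .psi_cache)
  .psi_cache[[key]] <- psi
  psi
}

#' Morlet continuous wavelet transform
#'
#' Complex wavelet coefficients of a series at each frequency of a linear
#' grid, on the input's own time grid. Coefficients near the segment ends
#' (within the cone of influence, `sqrt(2) * scale` seconds) are attenuated
#' by edge truncation; in the movement pipeline 3 s pads absorb this and
#' are cropped afterwards.
#'
#' @param x Numeric vector, or a data frame with `time_s` and one signal
#'   column.
#' @param grid [build_frequency_grid()].
#' @param wavenumber Morlet omega0.
#' @param fs Sampling rate, Hz (required when `x` is a bare vector).
#' @param col Signal column when `x` is a data frame with several.
#' @return Object of class `tf_map` holding a complex frequency-by-time
#'   matrix, the frequency and time grids, and the per-frequency cone-of-
#'   influence half-width (attribute `coi_s`).
#' @export
morlet_cwt <- function(x, grid, wavenumber = 10, fs = NULL, col = NULL) {
  if (is.data.frame(x)) {
    cl <- value_cols(x, col)
    if (length(cl) != 1L) abort("`x` must contain exactly one signal column (or pass `col`)")
    fs <- fs %||% ts_fs(x$time_s)
    t0 <- x$time_s[1]
    x <- x[[cl]]
  } else {
    if (is.null(fs)) abort("`fs` is required when `x` is a numeric vector")
    t0 <- 0
  }
  check_finite(x, "signal")
  n <- length(x)
  if (n < 2) abort("series too short")
  dt <- 1 / fs
  if (n * dt < 1 / min(grid$freq_hz)) {
    abort("series shorter than one period of the lowest grid frequency")
  }
  n2 <- 2^(ceiling(log2(n)) + 1)
  X <- stats::fft(c(x, rep(0, n2 - n)))
  psi <- morlet_spectra(grid$freq_hz, wavenumber, n2, dt)
  W <- stats::mvfft(psi * X, inverse = TRUE)[seq_len(n), , drop = FALSE] / n2
  tf_map(t(W), grid, time_s = t0 + (seq_len(n) - 1) * dt, kind = "cwt",
         coi_s = sqrt(2) * morlet_scale(grid$freq_hz, wavenumber))
}

# --- tf_map container ------------------------------------------------------

#' Time-frequency map
#'
#' Matrix over (frequency x time) with its grids: complex wavelet
#' coefficients or cross-spectra, real power, coherence, or a logical
#' significance mask.
#'
#' @param values Matrix, frequencies in rows.
#' @param grid [build_frequency_grid()] (or a `freq_grid` list).
#' @param time_s Time grid, s.
#' @param kind Short label: `"cwt"`, `"power"`, `"cross"`, `"msc"`, `"mask"`.
#' @param n_trials Number of trials averaged, if any.
#' @param coi_s Optional per-frequency cone-of-influence half-width, s.
#' @return Object of class `tf_map`.
#' @export
tf_map <- function(values, grid, time_s, kind = "power", n_trials = NULL, coi_s = NULL) {
  if (nrow(values) != length(grid$freq_hz) || ncol(values) != length(time_s)) {
    abort("tf_map dimensions do not match the frequency/time grids")
  }
  structure(list(values = values, freq_hz = grid$freq_hz, delta_f = grid$delta_f,
                 time_s = time_s, kind = kind, n_trials = n_trials, coi_s = coi_s),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map:%s> %d freqs (%.3g-%.5g Hz) x %d times (%.3g..%.3g s)%s\n",
              x$kind, length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              length(x$time_s), min(x$time_s), max(x$time_s),
              if (!is.null(x$n_trials)) sprintf(", %d trials", x$n_trials) else ""))
  invisible(x)
}

#' @export
tidy.tf_map <- function(x, ...) {
  v <- x$values
  tibble(freq_hz = rep(x$freq_hz, times = ncol(v)),
         time_s = rep(x$time_s, each = nrow(v)),
         value = as.vector(if (is.complex(v)) Mod(v)^2 else v))
}
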