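# shared small-scale fixtures: K noise trials at a coarse grid
coh_fixture <- function(K, n = 750, fs = 250, gain2 = NULL, seed = 3) {
  withr::with_seed(seed, {
    xs <- purrr::map(seq_len(K), ~ rnorm(n))
    ys <- if (is.null(gain2)) purrr::map(seq_len(K), ~ rnorm(n)) else
      purrr::map(xs, ~ gain2 * .x)
  })
  make_trial_table(xs, ys, fs)
}

test_that("self-coherence is 1 and coherence is amplitude-scale invariant", {
  grid <- toy_grid(seq(5, 60, by = 5))
  tr <- coh_fixture(20, gain2 = 1)
  sp <- trial_averaged_spectra(tr, c("emg1_v", "emg2_v"), grid)
  msc <- magnitude_squared_coherence(sp$cross, sp$auto1, sp$auto2)
  expect_true(all(abs(msc$values - 1) < 1e-9))

  tr2 <- coh_fixture(20)
  sp2 <- trial_averaged_spectra(tr2, c("emg1_v", "emg2_v"), grid)
  m2 <- magnitude_squared_coherence(sp2$cross, sp2$auto1, sp2$auto2)
  tr3 <- dplyr::mutate(tr2, emg = purrr::map(emg, ~ dplyr::mutate(.x, emg2_v = 7.3 * emg2_v)))
  sp3 <- trial_averaged_spectra(tr3, c("emg1_v", "emg2_v"), grid)
  m3 <- magnitude_squared_coherence(sp3$cross, sp3$auto1, sp3$auto2)
  expect_true(all(abs(m2$values - m3$values) < 1e-9))
  expect_true(all(m2$values >= 0 & m2$values <= 1))
})

test_that("single-trial coherence is rejected", {
  grid <- toy_grid(seq(5, 60, by = 5))
  tr <- coh_fixture(1)
  expect_error(trial_averaged_spectra(tr, c("emg1_v", "emg2_v"), grid), "at least 2")
})

test_that("independent trials give mean coherence near 1/K", {
  grid <- toy_grid(seq(5, 60, by = 5))
  for (K in c(5, 10, 20)) {
    tr <- coh_fixture(K, seed = K)
    sp <- trial_averaged_spectra(tr, c("emg1_v", "emg2_v"), grid)
    msc <- magnitude_squared_coherence(sp$cross, sp$auto1, sp$auto2)
    expect_equal(mean(msc$values), 1 / K, tolerance = 0.2)
  }
})

test_that("the analytic significance threshold matches 1 - alpha^(1/(K-1))", {
  grid <- toy_grid(seq(5, 60, by = 5))
  tr <- coh_fixture(20)
  sp <- trial_averaged_spectra(tr, c("emg1_v", "emg2_v"), grid)
  msc <- magnitude_squared_coherence(sp$cross, sp$auto1, sp$auto2)
  m20 <- coherence_significance_mask(msc, K = 20, alpha = 0.05)
  expect_equal(round(attr(m20, "threshold"), 4), 0.1459)
  m2 <- coherence_significance_mask(msc, K = 2, alpha = 0.05)
  expect_equal(attr(m2, "threshold"), 0.95)
  expect_error(coherence_significance_mask(msc, K = 20, alpha = 0), "alpha")
  expect_error(coherence_significance_mask(msc, K = 1), "K")
})

test_that("coherence is invariant to a common time shift of both channels", {
  fs <- 250
  n <- 750
  # lowest frequency 10 Hz: wavelet support ~0.96 s = 241 samples, so the
  # interior columns below see the full (untruncated) signal in both runs
  grid <- toy_grid(seq(10, 40, by = 5))
  withr::with_seed(8, {
    xs <- purrr::map(1:4, ~ rnorm(n + 50))
    ys <- purrr::map(xs, ~ 0.7 * .x + rnorm(n + 50))
  })
  tr_a <- make_trial_table(purrr::map(xs, ~ .x[1:n]), purrr::map(ys, ~ .x[1:n]), fs)
  tr_b <- make_trial_table(purrr::map(xs, ~ .x[51:(n + 50)]),
                           purrr::map(ys, ~ .x[51:(n + 50)]), fs)
  m_a <- wavelet_coherence(tr_a, c("emg1_v", "emg2_v"), grid = grid)
  m_b <- wavelet_coherence(tr_b, c("emg1_v", "emg2_v"), grid = grid)
  # interior cells (away from edges) agree despite the common 0.2 s shift
  int <- 300:450
  expect_equal(m_a$msc$values[, int + 0], m_b$msc$values[, int - 50],
               tolerance = 1e-6)
})

test_that("band volume follows its closed form, is mask-gated and additive", {
  grid <- toy_grid(seq(0.5, 79.5, by = 0.5), delta_f = 0.5)
  nt <- 201
  time_s <- seq(-0.2, 0, length.out = nt)
  dt <- diff(time_s)[1]
  vals <- matrix(0.5, length(grid$freq_hz), nt)
  msc <- tf_map(vals, grid, time_s, "msc", n_trials = 20)
  mask_all <- tf_map(matrix(TRUE, nrow(vals), nt), grid, time_s, "mask", 20)
  coh <- structure(list(msc = msc, mask = mask_all, threshold = 0.1459, K = 20,
                        pair = "toy", significance = "analytic"),
                   class = "imc_coherence")
  out <- imc_volume(coh, band = c(13, 31), window = c(-0.2, 0))
  nbins <- sum(grid$freq_hz >= 13 & grid$freq_hz <= 31)
  expect_equal(out$imc_volume, 0.5 * nbins * 0.5 * nt * dt)
  # near the continuum rectangle 0.5 * 18 Hz * 0.2 s = 1.8 (the discrete
  # sum has inclusive band/window endpoints: 18.5 Hz x 0.201 s)
  expect_equal(out$imc_volume, 1.8, tolerance = 0.035)

  # all-false mask: zero volume
  coh$mask <- tf_map(matrix(FALSE, nrow(vals), nt), grid, time_s, "mask", 20)
  expect_equal(imc_volume(coh, band = c(13, 31), window = c(-0.2, 0))$imc_volume, 0)

  # additive over disjoint bands and homogeneous in the coherence values
  coh$mask <- mask_all
  v_lo <- imc_volume(coh, band = c(13, 22), window = c(-0.2, 0))$imc_volume
  v_hi <- imc_volume(coh, band = c(22.01, 31), window = c(-0.2, 0))$imc_volume
  expect_equal(v_lo + v_hi, out$imc_volume, tolerance = 1e-12)
  coh2 <- coh
  coh2$msc$values <- 2 * coh2$msc$values
  expect_equal(imc_volume(coh2, band = c(13, 31), window = c(-0.2, 0))$imc_volume,
               2 * out$imc_volume, tolerance = 1e-12)

  expect_error(imc_volume(coh, band = c(31, 13), window = c(-0.2, 0)), "increasing")
  expect_error(imc_volume(coh, band = c(13, 31), window = c(1, 2)), "no time-frequency")
})

test_that("wavelet_coherence object is self-consistent and tidyable", {
  grid <- toy_grid(seq(5, 60, by = 5))
  tr <- coh_fixture(6)
  coh <- wavelet_coherence(tr, c("emg1_v", "emg2_v"), grid = grid)
  expect_s3_class(coh, "imc_coherence")
  expect_equal(coh$K, 6)
  expect_equal(dim(coh$msc$values), dim(coh$mask$values))
  td <- tidy(coh)
  expect_named(td, c("freq_hz", "time_s", "msc", "significant"))
  expect_equal(nrow(td), length(coh$msc$values))
  g <- glance(coh)
  expect_equal(g$threshold, 1 - 0.05^(1 / 5))

  # surrogate thresholding gives a broadly similar cutoff for independent noise
  cs <- wavelet_coherence(tr, c("emg1_v", "emg2_v"), grid = grid,
                          significance = "surrogate", n_surrogates = 20)
  expect_gt(cs$threshold, 0.2)
  expect_lt(cs$threshold, 0.9)
})
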