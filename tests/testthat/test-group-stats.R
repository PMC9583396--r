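long2 <- function(a, b) {
  tibble::tibble(value = c(a, b),
                 grp = rep(c("g1", "g2"), c(length(a), length(b))))
}

test_that("pooled t-test matches the reference implementation and hand-pooled d", {
  tt <- two_sample_t(long2(c(1, 2, 3, 4), c(3, 4, 5, 6)), "value", "grp")
  ref <- stats::t.test(c(1, 2, 3, 4), c(3, 4, 5, 6), var.equal = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$df, 6)
  # hand-computed pooled SD: sqrt(5/3); d = -2 / sqrt(5/3)
  expect_equal(tt$cohens_d, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(round(tt$statistic, 3), -2.191)
  expect_equal(round(tt$cohens_d, 3), -1.549)

  same <- two_sample_t(long2(c(1, 2, 3), c(3, 1, 2)), "value", "grp")
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$cohens_d, 0)

  expect_error(two_sample_t(long2(c(1, 1), c(1, 1)), "value", "grp"), "pooled variance")
  expect_error(two_sample_t(long2(1, c(1, 2)), "value", "grp"), "at least 2")
})

test_that("Box-Cox profile likelihood recovers canonical lambdas and preserves ranks", {
  y <- c(2, 5, 9, 14)
  forced <- boxcox_transform(y, lambda = 1)
  expect_equal(forced$values, y - 1)
  expect_equal(boxcox_transform(y, lambda = 0)$values, log(y))

  withr::with_seed(14, {
    ln <- exp(rnorm(5000))
    nm <- rnorm(5000, mean = 20, sd = 2)
  })
  expect_gt(boxcox_transform(ln)$lambda, -0.15)
  expect_lt(boxcox_transform(ln)$lambda, 0.15)
  l_norm <- boxcox_transform(nm)$lambda
  expect_gt(l_norm, 0.6)
  expect_lt(l_norm, 1.4)

  # cross-check the profile maximum against MASS::boxcox on a grid
  bc <- MASS::boxcox(ln ~ 1, lambda = seq(-0.5, 0.5, 0.001), plotit = FALSE)
  expect_equal(boxcox_transform(ln)$lambda, bc$x[which.max(bc$y)], tolerance = 0.01)

  # zeros handled by the half-minimum offset; ranks preserved
  withz <- c(0, 0.2, 0.8, 1.6, 3)
  tz <- boxcox_transform(withz)
  expect_equal(tz$offset, 0.1)
  expect_equal(rank(tz$values), rank(withz))
  expect_error(boxcox_transform(c(-1, 2, 3)), "positive")
})

test_that("type-III ANCOVA reduces to two-way ANOVA without covariates and flags imbalance", {
  d <- null_metrics(12, seed = 2)
  fit <- ancova_imc(d, c("paretic", "dominant"), covariates = character(),
                    boxcox = FALSE)
  oracle <- stats::aov(imc_volume ~ limb * pair, data = d)
  otab <- summary(oracle)[[1]]
  td <- tidy(fit)
  expect_equal(td$statistic[td$term == "limb"], otab[1, "F value"], tolerance = 1e-8)
  expect_equal(td$statistic[td$term == "pair"], otab[2, "F value"], tolerance = 1e-8)
  expect_equal(td$statistic[td$term == "limb:pair"], otab[3, "F value"], tolerance = 1e-8)
  expect_true(all(td$eta_sq_partial >= 0 & td$eta_sq_partial <= 1))

  expect_error(ancova_imc(d[-1, ], c("paretic", "dominant")), "unbalanced")
  expect_error(ancova_imc(d, c("paretic", "missing_limb")), "unbalanced")
})

test_that("a planted one-SD limb shift is detected with high power", {
  hits <- 0
  reps <- 120
  for (r in seq_len(reps)) {
    d <- null_metrics(24, seed = 4000 + r, limb_shift = stats::sd(rlnorm(500, 0, 0.5)))
    fit <- ancova_imc(d, c("paretic", "dominant"))
    hits <- hits + tidy(fit)$significant[tidy(fit)$term == "limb"]
  }
  expect_gt(hits / reps, 0.8)
})

test_that("partial Spearman handles antitone data, no covariates, and confounders", {
  d <- tibble::tibble(x = 1:20, y = -(1:20) + 0.0, z = rnorm(20))
  ps <- partial_spearman(d, "x", "y")
  expect_equal(tidy(ps)$rho[1], -1)
  expect_lt(tidy(ps)$p.value[1], 1e-10)

  withr::with_seed(6, d2 <- tibble::tibble(x = rnorm(60), y = rnorm(60), z = rnorm(60)))
  plain <- stats::cor(d2$x, d2$y, method = "spearman")
  expect_equal(tidy(partial_spearman(d2, "x", "y"))$rho[1], plain, tolerance = 1e-12)

  # association only through the covariate disappears after partialling
  rhos <- purrr::map_dbl(1:20, function(s) {
    withr::with_seed(700 + s, {
      z <- rnorm(500)
      dd <- tibble::tibble(z = z, x = z + rnorm(500), y = z + rnorm(500))
    })
    tidy(partial_spearman(dd, "x", "y", covariates = "z"))$rho[1]
  })
  expect_lt(max(abs(rhos)), 0.1)
  # and without partialling the association is strong
  withr::with_seed(701, {
    z <- rnorm(500)
    dd <- tibble::tibble(z = z, x = z + rnorm(500), y = z + rnorm(500))
  })
  expect_gt(tidy(partial_spearman(dd, "x", "y"))$rho[1], 0.3)

  expect_error(partial_spearman(tibble::tibble(x = rep(1, 10), y = 1:10), "x", "y"),
               "constant ranks")
})

test_that("the outlier rule removes extreme residuals and reports both variants", {
  withr::with_seed(9, {
    z <- rnorm(40)
    d <- tibble::tibble(z = z, x = z + rnorm(40, sd = 0.5), y = -z + rnorm(40, sd = 0.5))
  })
  d$x[1] <- 40  # forces an extreme rank residual
  ps <- partial_spearman(d, "x", "y", covariates = "z")
  td <- tidy(ps)
  expect_equal(nrow(td), 2)
  expect_true(1 %in% ps$outliers)
  expect_equal(td$n[td$variant == "outliers_removed"], 40 - length(ps$outliers))
})

test_that("demographic summaries reproduce the printed cohort statistics", {
  path <- system.file("extdata", "stroke_cohort_demographics.csv", package = "imcoh")
  demo <- readr::read_csv(path, show_col_types = FALSE)
  s <- demographics_summary(demo, c("age_years", "emnsa_64", "fugl_meyer_66"))
  emnsa <- s[s$variable == "emnsa_64", ]
  expect_equal(emnsa$n, 24)
  expect_equal(emnsa$mean, 48.875)
  expect_equal(round(emnsa$sd), 14)

  expect_error(demographics_summary(tibble::tibble(a = 1)), "fewer than 2")
})
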