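# Group-level inference: pooled t-test with Cohen's d, Box-Cox
# transformation, type-III ANCOVA with partial eta-squared, partial
# Spearman correlation with a residual-SE outlier rule, and demographic
# summaries.

#' Two-sample pooled-variance t-test with Cohen's d
#'
#' Classical independent-samples t-test with pooled variance
#' (`df = n1 + n2 - 2`), two-sided p-value, and Cohen's d with a 95%
#' normal-approximation confidence interval (Hedges' variance formula).
#'
#' @param data Data frame in long format.
#' @param response,group Column names (strings): numeric response and a
#'   two-level grouping column.
#' @return Object of class `imc_ttest` with [tidy()] and [glance()]
#'   methods.
#' @export
two_sample_t <- function(data, response, group) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels")
  a <- data[[response]][g == levels(g)[1]]
  b <- data[[response]][g == levels(g)[2]]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled variance")
  df <- n1 + n2 - 2
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * df))
  structure(list(statistic = tt, df = df, p.value = p, estimate = mean(a) - mean(b),
                 cohens_d = d, d_conf = d + c(-1, 1) * stats::qnorm(0.975) * se_d,
                 levels = levels(g), n = c(n1, n2),
                 d_ci_method = "normal approximation (Hedges)"),
            class = "imc_ttest")
}

#' @export
print.imc_ttest <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.3g, d = %.3f [%.2f, %.2f] (%s vs %s)\n",
              x$df, x$statistic, x$p.value, x$cohens_d, x$d_conf[1], x$d_conf[2],
              x$levels[1], x$levels[2]))
  invisible(x)
}

#' @export
tidy.imc_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p.value, cohens_d = x$cohens_d,
         d_conf.low = x$d_conf[1], d_conf.high = x$d_conf[2])
}

#' @export
glance.imc_ttest <- function(x, ...) tidy(x)

# Box-Cox kernel
bc_kernel <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Box-Cox transformation with profile-likelihood lambda
#'
#' `y(lambda) = (y^lambda - 1)/lambda` (log for `lambda = 0`), with lambda
#' chosen by profile maximum likelihood unless supplied. Values must be
#' positive; when zeros are present, half the smallest positive value is
#' added as an offset (recorded in the result).
#'
#' @param x Numeric values (>= 0; strictly positive after the offset).
#' @param lambda Optional fixed lambda.
#' @param offset Optional fixed additive offset; by default 0, or half the
#'   smallest positive value when zeros are present.
#' @return List of class `boxcox_transform`: `values`, `lambda`, `offset`.
#' @export
boxcox_transform <- function(x, lambda = NULL, offset = NULL) {
  check_finite(x, "values")
  if (is.null(offset)) {
    offset <- if (any(x == 0)) min(x[x > 0]) / 2 else 0
  }
  y <- x + offset
  if (any(y <= 0)) abort("Box-Cox requires positive values (after offset)")
  if (is.null(lambda)) {
    n <- length(y)
    slog <- sum(log(y))
    prof <- function(l) {
      z <- bc_kernel(y, l)
      -n / 2 * log(mean((z - mean(z))^2)) + (l - 1) * slog
    }
    lambda <- stats::optimize(prof, c(-3, 3), maximum = TRUE)$maximum
  }
  structure(list(values = bc_kernel(y, lambda), lambda = lambda, offset = offset),
            class = "boxcox_transform")
}

#' Two-by-two ANCOVA on coherence volumes
#'
#' Linear model of the (Box-Cox transformed) coherence volume on limb,
#' muscle pair, their interaction, and four covariates (mean elbow angle
#' and mean angular velocity over the quantification window, age, and the
#' antagonist co-contraction), with sum-to-zero factor coding and
#' type-III (partial) sums of squares, so each term's F is reported
#' adjusting for all others. Partial eta-squared is
#' `SS_term / (SS_term + SS_error)`. Requires a balanced limb-by-pair
#' design. Significance is flagged at a Bonferroni-style corrected level
#' (default 0.017 for three planned limb contrasts).
#'
#' @param metrics Long metrics table with columns `limb`, `pair`, the
#'   response and the covariates (one row per subject x limb x pair).
#' @param limbs Length-2 character: which limb contrast to fit.
#' @param response Response column (default `"imc_volume"`).
#' @param covariates Covariate columns.
#' @param alpha Corrected significance level.
#' @param boxcox Transform the response by [boxcox_transform()] first.
#' @return Object of class `imc_ancova` with [tidy()] / [glance()].
#' @export
ancova_imc <- function(metrics, limbs,
                       response = "imc_volume",
                       covariates = c("mean_angle_deg", "mean_velocity_dps", "age",
                                      "cocontraction_pct"),
                       alpha = 0.017, boxcox = TRUE) {
  need <- c("limb", "pair", response, covariates)
  miss <- setdiff(need, names(metrics))
  if (length(miss)) abort(sprintf("metrics table is missing column(s): %s",
                                  paste(miss, collapse = ", ")))
  d <- metrics[metrics$limb %in% limbs, , drop = FALSE]
  if (!nrow(d)) abort("no rows for the requested limbs")
  d$limb <- factor(d$limb, levels = limbs)
  d$pair <- factor(d$pair)
  cells <- table(d$limb, d$pair)
  if (nrow(cells) != 2 || ncol(cells) != 2 || length(unique(as.vector(cells))) != 1) {
    bad <- paste(sprintf("%s:%s=%d", rep(rownames(cells), ncol(cells)),
                         rep(colnames(cells), each = nrow(cells)), as.vector(cells)),
                 collapse = ", ")
    abort(sprintf("unbalanced 2x2 limb-by-pair design (%s)", bad))
  }
  bc <- NULL
  if (boxcox) {
    bc <- boxcox_transform(d[[response]])
    d$.y <- bc$values
  } else {
    d$.y <- d[[response]]
  }
  fml <- stats::reformulate(c("limb * pair", covariates), response = ".y")
  mod <- stats::lm(fml, data = d,
                   contrasts = list(limb = "contr.sum", pair = "contr.sum"))
  an <- car::Anova(mod, type = 3)
  tab <- as.data.frame(an)
  terms <- rownames(tab)
  keep <- !terms %in% c("(Intercept)", "Residuals")
  ss_err <- tab["Residuals", "Sum Sq"]
  df_err <- tab["Residuals", "Df"]
  res <- tibble(
    term = terms[keep],
    df = tab$Df[keep],
    sumsq = tab$`Sum Sq`[keep],
    statistic = tab$`F value`[keep],
    p.value = tab$`Pr(>F)`[keep],
    eta_sq_partial = tab$`Sum Sq`[keep] / (tab$`Sum Sq`[keep] + ss_err),
    significant = tab$`Pr(>F)`[keep] < alpha)
  structure(list(terms = res, model = mod, alpha = alpha, limbs = limbs,
                 boxcox = bc, df_error = df_err, n = nrow(d),
                 ss_type = "III (sum-to-zero coding)"),
            class = "imc_ancova")
}

#' @export
print.imc_ancova <- function(x, ...) {
  cat(sprintf("<imc_ancova> %s vs %s (n = %d, type %s, alpha = %g)\n",
              x$limbs[1], x$limbs[2], x$n, x$ss_type, x$alpha))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' @export
tidy.imc_ancova <- function(x, ...) x$terms

#' @export
glance.imc_ancova <- function(x, ...) {
  tibble(n = x$n, df_error = x$df_error, alpha = x$alpha,
         boxcox_lambda = if (!is.null(x$boxcox)) x$boxcox$lambda else NA_real_,
         boxcox_offset = if (!is.null(x$boxcox)) x$boxcox$offset else NA_real_,
         ss_type = x$ss_type)
}

# one partial Spearman fit on a subset; k = number of covariates
partial_spearman_fit <- function(x, y, Z) {
  n <- length(x)
  k <- if (is.null(Z)) 0L else ncol(Z)
  rx <- rank(x); ry <- rank(y)
  if (length(unique(rx)) < 2 || length(unique(ry)) < 2) abort("constant ranks")
  if (k > 0) {
    RZ <- apply(Z, 2, rank)
    mx <- stats::lm.fit(cbind(1, RZ), rx)
    my <- stats::lm.fit(cbind(1, RZ), ry)
    ex <- mx$residuals; ey <- my$residuals
  } else {
    ex <- rx - mean(rx); ey <- ry - mean(ry)
    mx <- my <- NULL
  }
  rho <- stats::cor(ex, ey)
  df <- n - 2 - k
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  z <- atanh(max(min(rho, 1 - 1e-15), -1 + 1e-15))
  sez <- 1 / sqrt(n - 3 - k)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * sez)
  list(rho = rho, p = p, ci = ci, n = n, k = k, ex = ex, ey = ey)
}

#' Partial Spearman correlation with a residual-SE outlier rule
#'
#' Rank-transforms all variables, regresses the x- and y-ranks on the
#' covariate ranks, and correlates the two residual series (partial rho).
#' The p-value uses a t reference with `n - 2 - k` degrees of freedom and
#' the 95% CI a Fisher z transform. The analysis is reported twice: on all
#' points and after removing points whose residual exceeds two residual
#' standard errors in either rank regression (points re-ranked on the
#' retained subset).
#'
#' @param data Data frame.
#' @param x,y Column names of the two variables.
#' @param covariates Character vector of covariate columns (may be empty,
#'   giving the plain Spearman correlation).
#' @param outlier_se Residual-SE multiple defining an outlier (default 2).
#' @return Object of class `imc_partial_spearman`; [tidy()] returns one
#'   row per variant (`"all"`, `"outliers_removed"`).
#' @export
partial_spearman <- function(data, x, y, covariates = character(), outlier_se = 2) {
  xv <- data[[x]]; yv <- data[[y]]
  Z <- if (length(covariates)) as.matrix(data[, covariates, drop = FALSE]) else NULL
  n <- length(xv)
  k <- length(covariates)
  if (n <= k + 3) abort("need n > k + 3 observations")
  full <- partial_spearman_fit(xv, yv, Z)
  se_x <- sqrt(sum(full$ex^2) / (n - 1 - k))
  se_y <- sqrt(sum(full$ey^2) / (n - 1 - k))
  out <- abs(full$ex) > outlier_se * se_x | abs(full$ey) > outlier_se * se_y
  reduced <- NULL
  if (any(out) && sum(!out) > k + 3) {
    reduced <- partial_spearman_fit(xv[!out], yv[!out],
                                    if (is.null(Z)) NULL else Z[!out, , drop = FALSE])
  }
  structure(list(full = full, reduced = reduced, outliers = which(out),
                 outlier_se = outlier_se, vars = c(x = x, y = y),
                 covariates = covariates),
            class = "imc_partial_spearman")
}

#' @export
print.imc_partial_spearman <- function(x, ...) {
  f <- x$full
  cat(sprintf("partial Spearman %s ~ %s | %s\n", x$vars["x"], x$vars["y"],
              if (length(x$covariates)) paste(x$covariates, collapse = " + ") else "(none)"))
  cat(sprintf("  all points (n=%d): rho = %.3f, 95%% CI [%.2f, %.2f], p = %.3g\n",
              f$n, f$rho, f$ci[1], f$ci[2], f$p))
  if (!is.null(x$reduced)) {
    r <- x$reduced
    cat(sprintf("  outliers removed (%s): rho = %.3f, 95%% CI [%.2f, %.2f], p = %.3g\n",
                paste(x$outliers, collapse = ","), r$rho, r$ci[1], r$ci[2], r$p))
  } else cat("  no outliers beyond the rule\n")
  invisible(x)
}

#' @export
tidy.imc_partial_spearman <- function(x, ...) {
  row <- function(f, variant) {
    tibble(variant = variant, rho = f$rho, conf.low = f$ci[1], conf.high = f$ci[2],
           p.value = f$p, n = f$n, n_outliers = length(x$outliers))
  }
  out <- row(x$full, "all")
  if (!is.null(x$reduced)) out <- bind_rows(out, row(x$reduced, "outliers_removed"))
  out
}

#' Mean-and-SD demographic summary
#'
#' Arithmetic mean and sample SD (n-1 denominator) of each numeric column,
#' with the integer-rounded "mean +/- SD" string conventional in cohort
#' tables.
#'
#' @param data Data frame of per-subject values.
#' @param cols Columns to summarise; default all numeric columns.
#' @return Tibble: `variable`, `n`, `mean`, `sd`, `printed`.
#' @export
demographics_summary <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (!length(cols)) abort("no numeric columns to summarise")
  rows <- purrr::map(cols, function(cl) {
    v <- data[[cl]]
    v <- v[!is.na(v)]
    if (length(v) < 2) abort(sprintf("column %s has fewer than 2 values; SD undefined", cl))
    tibble(variable = cl, n = length(v), mean = mean(v), sd = stats::sd(v),
           printed = sprintf("%d ± %d", round(mean(v)), round(stats::sd(v))))
  })
  bind_rows(rows)
}
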