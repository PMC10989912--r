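# Regression-based variance tests: SVLM, CLS, DRM, Z-score. These operate
# on the additive 0/1/2 genotype coding and support covariates where the
# original methods do.

# Closed-form simple regression of y on an intercept + x with the
# two-sided Wald t-test for the slope. Lean on purpose: the Monte-Carlo
# engine calls this hundreds of thousands of times.
ols_slope_test <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  df <- n - 2
  if (sxx <= 0 || syy <= 0)
    return(list(slope = 0, t = 0, p = 1, df = df, degenerate = TRUE))
  slope <- sum(xc * yc) / sxx
  rss <- syy - slope^2 * sxx
  # a numerically perfect fit: the t reference is meaningless
  if (rss <= 1e-14 * syy)
    return(list(slope = slope, t = Inf, p = 0, df = df, degenerate = TRUE))
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  list(slope = slope, t = tval, p = 2 * pt(abs(tval), df, lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

# OLS residuals of y on intercept + g + covariates, with a collinearity
# error naming the offending column (shared stage 1 of SVLM and CLS).
stage1_residuals <- function(y, g, covariates) {
  X <- as_covariate_matrix(covariates, length(y))
  n_reg <- ncol(X) + 2L
  if (length(y) <= n_reg + 2L)
    stopf("n = %d is too small for %d regressors", length(y), n_reg)
  X <- cbind(`(Intercept)` = 1, genotype = as.numeric(g), X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("rank-deficient stage-1 design: column(s) %s are collinear",
          paste(dropped, collapse = ", "))
  }
  qr.resid(qx, y)
}

#' Squared residual value linear model (SVLM)
#'
#' Stage 1 regresses the trait on an intercept, the genotype and any
#' covariates, removing the genetic effect on the mean; stage 2 regresses
#' the squared stage-1 residuals on the genotype. The two-sided Wald
#' t-test for the stage-2 genotype slope detects a variance effect, and
#' that slope is reported as the effect size (the allele effect on the
#' squared residual of the trait).
#'
#' @param y numeric trait vector.
#' @param g genotype vector coded 0/1/2.
#' @param covariates optional covariates for stage 1.
#' @return A `vqtl_test` result. A deterministic trait (all stage-1
#'   residuals zero) yields the degenerate convention p = 1, effect 0,
#'   with a note.
#' @examples
#' g <- rep(0:2, each = 30)
#' y <- rnorm(90, sd = 1 + 0.3 * g)
#' svlm_test(y, g)
#' @export
svlm_test <- function(y, g, covariates = NULL) {
  check_yg(y, g)
  r <- stage1_residuals(y, g, covariates)
  if (sum(r^2) <= 1e-20 * max(1, sum(y^2)))
    return(new_test_result("svlm", statistic = 0, p_value = 1,
                           effect_size = 0, df = length(y) - 2,
                           note = "degenerate: trait is deterministic in the regressors"))
  fit <- ols_slope_test(r^2, as.numeric(g))
  new_test_result("svlm", statistic = fit$t, p_value = fit$p,
                  effect_size = fit$slope, df = fit$df)
}

#' Correlation least squares test (CLS)
#'
#' Regresses the trait on the genotype (plus covariates) as in SVLM, then
#' tests the Spearman rank correlation between the squared residuals and
#' the genotype, using the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with average ranks for ties.
#'
#' @inheritParams svlm_test
#' @return A `vqtl_test` result with the correlation as statistic (and as
#'   effect size slot left empty: the method reports no genotype
#'   coefficient). Constant squared residuals give the p = 1 convention.
#' @examples
#' g <- rep(0:2, each = 30)
#' y <- rnorm(90, sd = 1 + 0.3 * g)
#' cls_test(y, g)
#' @export
cls_test <- function(y, g, covariates = NULL) {
  check_yg(y, g)
  r <- stage1_residuals(y, g, covariates)
  r2 <- r^2
  if (sum(r2) <= 1e-20 * max(1, sum(y^2)) || sd(r2) == 0 || sd(g) == 0)
    return(new_test_result("cls", statistic = 0, p_value = 1,
                           df = length(y) - 2,
                           note = "degenerate: constant squared residuals"))
  rho <- cor(rank(r2), rank(g))
  n <- length(y)
  if (abs(rho) >= 1)
    return(new_test_result("cls", statistic = rho, p_value = 0, df = n - 2))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  new_test_result("cls", statistic = rho,
                  p_value = 2 * pt(abs(tval), n - 2, lower.tail = FALSE),
                  df = n - 2)
}

#' Deviation regression model (DRM)
#'
#' Regresses the absolute distance of each trait value from its genotype
#' group's median on the additive genotype coding. The Wald t-test of the
#' slope detects a variance effect; the slope (allele effect on the
#' median-centered deviation) is the effect size.
#'
#' @inheritParams svlm_test
#' @return A `vqtl_test` result.
#' @examples
#' drm_test(c(1, 2, 3, 0, 4, 8), c(0, 0, 0, 2, 2, 2))
#' @export
drm_test <- function(y, g) {
  f <- genotype_groups(y, g, min_per_group = 1L)
  d <- abs(y - tapply(y, f, median)[f])
  fit <- ols_slope_test(d, as.numeric(g))
  note <- if (fit$degenerate) "degenerate regression" else NULL
  new_test_result("drm", statistic = fit$t, p_value = fit$p,
                  effect_size = fit$slope, df = fit$df, note = note)
}

#' Z-score regression test
#'
#' Applies the rank inverse-normal transformation to the trait, squares
#' the resulting normal scores, and regresses them on the genotype. The
#' squared score is a rank-based measure of distance from the distribution
#' center, so a genotype effect on it indicates a variance effect — but
#' the internal transformation also converts mean effects into apparent
#' variance effects, which is why this test shows a high false positive
#' rate in the presence of mean-controlling QTLs.
#'
#' @inheritParams svlm_test
#' @return A `vqtl_test` result with the genotype slope as effect size.
#' @examples
#' g <- rep(0:2, each = 30)
#' zscore_test(rnorm(90), g)
#' @export
zscore_test <- function(y, g) {
  check_yg(y, g)
  if (length(y) < 10L) stopf("the Z-score test needs n >= 10")
  z2 <- rank_int(y)^2
  fit <- ols_slope_test(z2, as.numeric(g))
  new_test_result("zscore", statistic = fit$t, p_value = fit$p,
                  effect_size = fit$slope, df = fit$df)
}
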