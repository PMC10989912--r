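# Regression-based variance tests: SVLM, CLS, DRM, Z-score.

test_that("SVLM matches a two-stage closed-form oracle on a 9-point fixture", {
  g <- c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  y <- c(-0.1, 0.0, 0.2, -0.6, 0.1, 0.8, -1.5, 0.3, 1.9)
  # oracle: two sequential simple regressions from textbook formulas
  s1 <- simple_lm_oracle(y, g)
  r <- y - (mean(y) - s1$slope * mean(g)) - s1$slope * g
  s2 <- simple_lm_oracle(r^2, g)
  res <- svlm_test(y, g)
  expect_equal(res$effect_size, s2$slope, tolerance = 1e-10)
  expect_equal(res$statistic, s2$t, tolerance = 1e-10)
  expect_equal(res$p_value, s2$p, tolerance = 1e-10)
  expect_gt(res$effect_size, 0)  # spread widens with g by construction
})

test_that("SVLM degenerates gracefully and rejects collinear covariates", {
  g <- rep(0:2, each = 4)
  res <- svlm_test(2 * g + 1, g)
  expect_equal(res$p_value, 1)
  expect_match(res$note, "deterministic")
  set.seed(7)
  y <- rnorm(12)
  expect_error(svlm_test(y, g, covariates = cbind(gdup = g)), "collinear")
})

test_that("CLS recovers perfect monotone agreement and the rank-formula p-value", {
  # tied ranks align exactly: rho = 1
  y2 <- c(1, 1, 2, 2, 3, 3); g <- c(0, 0, 1, 1, 2, 2)
  r2 <- y2  # feed squared residuals directly through a trick fixture:
  # construct y so that stage-1 residuals^2 are y2: use g-free y with
  # known deviations. Simpler: check the rank correlation core on an
  # anti-monotone fixture through the public interface below.
  rho <- cor(rank(r2), rank(g))
  expect_equal(rho, 1)

  # 8-point untied fixture via the public interface, against the
  # definition 1 - 6*sum(d^2)/(n(n^2-1)) on the realized ranks
  set.seed(8)
  g8 <- c(0, 0, 1, 1, 1, 2, 2, 2)
  y8 <- rnorm(8, sd = 1 + g8)
  res <- cls_test(y8, g8)
  r <- resid(lm(y8 ~ g8))
  rk1 <- rank(r^2); rk2 <- rank(g8)
  rho_def <- 1 - 6 * sum((rk1 - rk2)^2) / (8 * 63)
  # with ties in g the average-rank Pearson form is the reference; the
  # d^2 identity holds exactly only untied, so compare to cor on ranks
  expect_equal(res$statistic, cor(rk1, rk2), tolerance = 1e-12)
  tref <- res$statistic * sqrt(6 / (1 - res$statistic^2))
  expect_equal(res$p_value, 2 * pt(abs(tref), 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # untied-rank case: d^2 identity applies
  gu <- 1:8
  yu <- rnorm(8)
  resu <- cls_test(yu, gu)
  ru <- resid(lm(yu ~ gu))
  du <- rank(ru^2) - rank(gu)
  expect_equal(resu$statistic, 1 - 6 * sum(du^2) / (8 * 63), tolerance = 1e-12)
})

test_that("CLS flags constant squared residuals", {
  g <- rep(0:2, each = 4)
  res <- cls_test(2 * g, g)
  expect_equal(res$p_value, 1)
  expect_match(res$note, "degenerate")
})

test_that("DRM reproduces the closed-form slope on the printed fixture", {
  y <- c(1, 2, 3, 0, 4, 8); g <- c(0, 0, 0, 2, 2, 2)
  d <- c(1, 0, 1, 4, 0, 4)  # median-centered distances, by hand
  res <- drm_test(y, g)
  expect_equal(res$effect_size, cov(d, g) / var(g), tolerance = 1e-12)
  s <- simple_lm_oracle(d, g)
  expect_equal(res$p_value, s$p, tolerance = 1e-10)
  # identical distance multisets: slope 0, p 1
  res0 <- drm_test(c(1, 3, 11, 13), c(0, 0, 1, 1))
  expect_equal(res0$effect_size, 0)
  expect_equal(res0$p_value, 1)
})

test_that("DRM is scale-equivariant in the effect and scale-invariant in p", {
  co <- scale_cohort(n = 100, seed = 9)
  r1 <- drm_test(co$y, co$g)
  r2 <- drm_test(3.7 * co$y, co$g)
  expect_equal(r2$effect_size, 3.7 * r1$effect_size, tolerance = 1e-10)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
})

test_that("Z-score regression matches the explicit score-table oracle", {
  set.seed(10)
  y <- rnorm(12); g <- rep(0:2, each = 4)
  n <- 12
  scores2 <- qnorm((rank(y) - 0.5) / n)^2
  s <- simple_lm_oracle(scores2, g)
  res <- zscore_test(y, g)
  expect_equal(res$statistic, s$t, tolerance = 1e-10)
  expect_equal(res$p_value, s$p, tolerance = 1e-10)
  expect_equal(res$effect_size, s$slope, tolerance = 1e-10)
})

test_that("Z-score regression is invariant to sample order and errors on ties", {
  set.seed(11)
  y <- rnorm(30); g <- rbinom(30, 2, 0.4)
  res <- zscore_test(y, g)
  idx <- sample(30)
  resp <- zscore_test(y[idx], g[idx])
  expect_equal(resp$statistic, res$statistic, tolerance = 1e-12)
  expect_error(zscore_test(rep(1, 30), g), "identical")
  expect_error(zscore_test(rnorm(8), rbinom(8, 2, 0.5)), "n >= 10")
})

test_that("p-values are invariant to positive rescaling of the trait", {
  co <- scale_cohort(n = 120, seed = 12)
  e <- rnorm(120)
  for (m in c("levene", "bf", "bartlett", "fk", "svlm", "cls", "drm",
              "zscore")) {
    p1 <- run_method(m, co$y, co$g, covariates = e)$p_value
    p2 <- run_method(m, 5.1 * co$y, co$g, covariates = e)$p_value
    expect_equal(p2, p1, tolerance = 1e-10)
  }
  # DGLM's log-link dispersion model: the genotype coefficient is
  # scale-free (scaling shifts only the intercept)
  d1 <- dglm_test(co$y, co$g)
  d2 <- dglm_test(5.1 * co$y, co$g)
  expect_equal(d2$effect_size, d1$effect_size, tolerance = 1e-6)
})
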