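# Group-based variance tests against independent oracles.

test_that("equal within-group spread gives F = 0, p = 1 for Levene/BF", {
  for (ctr in c("mean", "median")) {
    res <- center_distance_anova(c(1, 3, 1, 3), c(0, 0, 1, 1), center = ctr)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
})

test_that("the median-centered distance ANOVA matches a direct fixture computation", {
  y <- c(1, 2, 3, 0, 4, 8); g <- c(0, 0, 0, 1, 1, 1)
  # oracle: the distances are [1,0,1,4,0,4]; run a plain one-way ANOVA on
  # them with lm/anova, independent of the package arithmetic
  d <- c(1, 0, 1, 4, 0, 4)
  fit <- anova(lm(d ~ factor(g)))
  res <- center_distance_anova(y, g, center = "median")
  expect_equal(res$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, fit$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Levene and BF agree with car::leveneTest on random cohorts", {
  set.seed(4)
  for (i in 1:3) {
    co <- scale_cohort(n = 120, seed = i)
    fg <- factor(co$g)
    lev <- car::leveneTest(co$y, fg, center = mean)
    bf <- car::leveneTest(co$y, fg, center = median)
    expect_equal(center_distance_anova(co$y, co$g, "mean")$statistic,
                 lev[1, "F value"], tolerance = 1e-10)
    expect_equal(center_distance_anova(co$y, co$g, "median")$p_value,
                 bf[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("degenerate genotype layouts are rejected", {
  expect_error(center_distance_anova(1:5, rep(1, 5)), "single genotype group")
  expect_error(center_distance_anova(1:5, c(0, 0, 0, 0, 1)), "fewer than 2")
})

test_that("Bartlett's statistic matches the closed form and stats::bartlett.test", {
  # equal variances annihilate the log ratio
  res <- bartlett_test(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  y <- c(1, 2, 3, 4, 10, 20, 30, 40); g <- rep(0:1, each = 4)
  # oracle: direct evaluation with s1^2 = 5/3, s2^2 = 500/3
  sp2 <- (3 * 5 / 3 + 3 * 500 / 3) / 6
  num <- 6 * log(sp2) - 3 * log(5 / 3) - 3 * log(500 / 3)
  den <- 1 + (1 / 3 + 1 / 3 - 1 / 6) / 3
  res <- bartlett_test(y, g)
  expect_equal(res$statistic, num / den, tolerance = 1e-10)
  ref <- bartlett.test(y, factor(g))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(bartlett_test(c(1, 2, 3, 4), c(0, 0, 0, 1)), "fewer than 2")
  expect_error(bartlett_test(c(1, 1, 2, 3), c(0, 0, 1, 1)), "zero variance")
})

test_that("Fligner-Killeen handles symmetric and degenerate inputs", {
  # identical distance multisets across groups
  res <- fligner_killeen_test(c(1, 3, 2, 4, 6, 5), c(0, 0, 0, 1, 1, 1))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # all distances tie: zero score variance convention
  res <- fligner_killeen_test(c(1, 3, 1, 3), c(0, 0, 1, 1))
  expect_equal(res$p_value, 1)
  expect_match(res$note, "identical")
})

test_that("Fligner-Killeen matches stats::fligner.test", {
  # 8-point fixture with unequal spreads
  y <- c(0, 1, 2, 3, -5, 0, 5, 10); g <- rep(0:1, each = 4)
  ref <- fligner.test(y, factor(g))
  res <- fligner_killeen_test(y, g)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  set.seed(5)
  for (i in 1:3) {
    co <- scale_cohort(n = 90, seed = 10 + i)
    ref <- fligner.test(co$y, factor(co$g))
    res <- fligner_killeen_test(co$y, co$g)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("group tests are invariant to location shifts", {
  co <- scale_cohort(n = 80, seed = 6)
  for (fn in list(function(y, g) center_distance_anova(y, g, "mean")$statistic,
                  function(y, g) center_distance_anova(y, g, "median")$statistic,
                  function(y, g) bartlett_test(y, g)$statistic,
                  function(y, g) drm_test(y, g)$statistic)) {
    expect_equal(fn(co$y + 17.3, co$g), fn(co$y, co$g), tolerance = 1e-10)
  }
  # FK ranks the distances, and exact distance ties (even-sized groups
  # place two points symmetrically around the median) are fragile under
  # floating-point shifts; dyadic-rational data keeps them exact
  yq <- round(co$y * 4) / 4
  expect_equal(fligner_killeen_test(yq + 17.25, co$g)$statistic,
               fligner_killeen_test(yq, co$g)$statistic, tolerance = 1e-10)
})
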