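# Group-based variance heterogeneity tests: Levene, Brown-Forsythe,
# Bartlett, Fligner-Killeen. All treat the genotype as a factor with G
# levels and compare within-group spread.

#' Levene / Brown-Forsythe test via ANOVA on center distances
#'
#' Computes per-sample distances `Z_gi = |y_gi - center_g|`, where
#' `center_g` is the within-group mean (Levene's test) or median
#' (Brown-Forsythe), and applies a one-way ANOVA of the distances across
#' genotype groups. The F statistic is referred to the F distribution with
#' `(G - 1, N - G)` degrees of freedom.
#'
#' @param y numeric trait vector.
#' @param g genotype vector (coerced to a factor; 0/1/2 coding expected).
#' @param center `"mean"` (Levene) or `"median"` (Brown-Forsythe).
#' @return A `vqtl_test` result. If all distances are identical within and
#'   between groups the statistic is 0 and p = 1.
#' @examples
#' center_distance_anova(c(1, 2, 3, 0, 4, 8), c(0, 0, 0, 1, 1, 1), "median")
#' @export
center_distance_anova <- function(y, g, center = c("mean", "median")) {
  center <- match.arg(center)
  f <- genotype_groups(y, g)
  centers <- if (center == "mean") tapply(y, f, mean) else tapply(y, f, median)
  z <- abs(y - centers[f])
  n <- length(z); G <- nlevels(f)
  ng <- tabulate(f)
  zg <- tapply(z, f, mean)
  zbar <- mean(z)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((z - zg[f])^2)
  if (ss_within <= 0) {
    if (ss_between <= 0)
      return(new_test_result(if (center == "mean") "levene" else "bf",
                             statistic = 0, p_value = 1, df = G - 1,
                             note = "degenerate: all distances equal"))
    return(new_test_result(if (center == "mean") "levene" else "bf",
                           statistic = Inf, p_value = 0, df = G - 1,
                           note = "zero within-group distance variance"))
  }
  stat <- (n - G) / (G - 1) * ss_between / ss_within
  new_test_result(if (center == "mean") "levene" else "bf",
                  statistic = stat,
                  p_value = pf(stat, G - 1, n - G, lower.tail = FALSE),
                  df = G - 1)
}

#' Bartlett's test of equal group variances
#'
#' The log-ratio of the pooled variance to the within-group variances,
#' normalized by the usual correction factor, is referred to a chi-squared
#' distribution with `G - 1` degrees of freedom. Bartlett's statistic is a
#' modified likelihood-ratio statistic and is well known to be sensitive
#' to non-normality (its size is driven by kurtosis), which is exactly the
#' behaviour the benchmark probes with skewed error distributions.
#'
#' @inheritParams center_distance_anova
#' @return A `vqtl_test` result.
#' @examples
#' bartlett_test(c(1, 2, 3, 4, 10, 20, 30, 40), rep(0:1, each = 4))
#' @export
bartlett_test <- function(y, g) {
  f <- genotype_groups(y, g)
  n <- length(y); G <- nlevels(f)
  ng <- tabulate(f)
  s2 <- tapply(y, f, var)
  if (any(s2 <= 0))
    stopf("genotype group '%s' has zero variance: Bartlett's statistic is undefined (log of zero)",
          levels(f)[which(s2 <= 0)[1L]])
  sp2 <- sum((ng - 1) * s2) / (n - G)
  num <- (n - G) * log(sp2) - sum((ng - 1) * log(s2))
  den <- 1 + (sum(1 / (ng - 1)) - 1 / (n - G)) / (3 * (G - 1))
  stat <- num / den
  new_test_result("bartlett", statistic = stat,
                  p_value = pchisq(stat, G - 1, lower.tail = FALSE),
                  df = G - 1)
}

#' Fligner-Killeen test (median-centered rank variant)
#'
#' The modified Fligner-Killeen test ranks the absolute distances
#' `|y_gi - median_g|` over all samples, maps the ranks through the
#' standard normal quantile function `qnorm(1/2 + rank / (2 * (N + 1)))`
#' (average ranks for ties), and compares group means of these normal
#' scores with the statistic `sum(N_g * (A_g - a)^2) / sigma^2`, referred
#' to chi-squared with `G - 1` degrees of freedom; `sigma^2` is the sample
#' variance of all scores.
#'
#' @inheritParams center_distance_anova
#' @return A `vqtl_test` result. When every score is identical (all
#'   distances tied) the statistic is undefined; the convention here is
#'   statistic 0, p = 1, with an explanatory note.
#' @examples
#' fligner_killeen_test(c(1, 3, 2, 4, 6, 5), c(0, 0, 0, 1, 1, 1))
#' @export
fligner_killeen_test <- function(y, g) {
  f <- genotype_groups(y, g)
  n <- length(y); G <- nlevels(f)
  z <- abs(y - tapply(y, f, median)[f])
  a <- qnorm(0.5 + rank(z, ties.method = "average") / (2 * (n + 1)))
  s2 <- var(a)
  if (s2 <= 0)
    return(new_test_result("fk", statistic = 0, p_value = 1, df = G - 1,
                           note = "degenerate: all normal scores identical"))
  ng <- tabulate(f)
  ag <- tapply(a, f, mean)
  stat <- sum(ng * (ag - mean(a))^2) / s2
  new_test_result("fk", statistic = stat,
                  p_value = pchisq(stat, G - 1, lower.tail = FALSE),
                  df = G - 1)
}
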