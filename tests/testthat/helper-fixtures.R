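# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A cohort with y independent of g (exchangeable null).
null_cohort <- function(n = 300, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- simulate_genotypes(n, maf)
  list(y = rnorm(n), g = g)
}

# A cohort whose trait standard deviation grows linearly in the genotype.
scale_cohort <- function(n = 300, maf = 0.3, slope = 0.5, seed = 1) {
  set.seed(seed)
  g <- simulate_genotypes(n, maf)
  list(y = rnorm(n, sd = 1 + slope * g), g = g)
}

# Closed-form simple regression oracle: slope, t and two-sided p of y on
# an intercept + x, straight from the textbook formulas.
simple_lm_oracle <- function(y, x) {
  n <- length(y)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  t <- b / se
  list(slope = b, t = t, p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}
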