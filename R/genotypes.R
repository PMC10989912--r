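#' Simulate genotypes at a single biallelic locus
#'
#' Genotypes are coded 0/1/2 as the number of minor alleles. Group sizes
#' follow Hardy-Weinberg proportions `((1-maf)^2, 2*maf*(1-maf), maf^2)`,
#' and every genotype class must contain at least `min_group` samples — the
#' guard the benchmark applies so that spurious variance signals from tiny
#' genotype classes (e.g. parent-of-origin effects) cannot arise.
#'
#' Two sampling policies are available. `"fixed"` (the default, and the one
#' the simulation grids use) determines the three group sizes
#' deterministically from `n` and `maf`: expected Hardy-Weinberg counts are
#' rounded, any class below `min_group` is raised to `min_group` and the
#' deficit is taken from the largest class; sample order is then shuffled.
#' This keeps scenarios with a rare minor homozygote class (e.g. n = 1000,
#' MAF 0.05, expected count 2.5) feasible while honouring the group-size
#' floor. `"multinomial"` draws the class counts from the multinomial
#' distribution and rejection-resamples whole vectors until the floor
#' holds; when the expected minor-homozygote count `maf^2 * n` is far below
#' `min_group` the cap of `max_attempts` draws is exhausted and an error
#' reports that expectation.
#'
#' @param n sample size, at least `3 * min_group`.
#' @param maf minor allele frequency in (0, 0.5].
#' @param min_group minimum samples per genotype class (default 10).
#' @param seed optional integer seed.
#' @param sampling `"fixed"` or `"multinomial"` (see Details).
#' @param max_attempts rejection-sampling cap for `"multinomial"`.
#' @return An integer vector of length `n` with values in `{0, 1, 2}`.
#' @examples
#' g <- simulate_genotypes(1000, maf = 0.05, seed = 1)
#' table(g)  # minor homozygotes floored at 10
#' @export
simulate_genotypes <- function(n, maf, min_group = 10, seed = NULL,
                               sampling = c("fixed", "multinomial"),
                               max_attempts = 1000) {
  sampling <- match.arg(sampling)
  check_scalar_number(n, "n"); check_scalar_number(maf, "maf")
  n <- as.integer(n); min_group <- as.integer(min_group)
  if (maf <= 0 || maf > 0.5)
    stopf("'maf' must lie in (0, 0.5], got %g (a degenerate locus has no minor allele)", maf)
  if (n < 3 * min_group)
    stopf("n = %d is below 3 * min_group = %d", n, 3L * min_group)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

  if (sampling == "fixed") {
    counts <- round(p * n)
    counts[1] <- n - counts[2] - counts[3]   # absorb rounding in largest class
    low <- counts < min_group
    if (any(low)) {
      deficit <- sum(min_group - counts[low])
      counts[low] <- min_group
      big <- which.max(counts)
      counts[big] <- counts[big] - deficit
    }
    if (any(counts < min_group))
      stopf("cannot allocate %d samples into three groups of at least %d", n, min_group)
    return(sample(rep.int(0:2, counts)))
  }

  expected_minor_hom <- p[3] * n
  for (attempt in seq_len(max_attempts)) {
    counts <- drop(rmultinom(1, n, p))
    if (all(counts >= min_group))
      return(sample(rep.int(0:2, counts)))
  }
  stopf(paste0(
    "no multinomial draw satisfied >= %d samples per genotype class in %d ",
    "attempts: at n = %d, MAF = %g the expected minor-homozygote count is ",
    "%.3g; use sampling = \"fixed\" or a larger n/MAF"),
    min_group, max_attempts, n, maf, expected_minor_hom)
}
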