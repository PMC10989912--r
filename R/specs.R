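#' Describe the environmental exposure of a simulated cohort
#'
#' An exposure specification captures the distribution of the single
#' environmental factor `E` entering the gene-by-environment trait model.
#' Three families are supported: a binary exposure with a fixed fraction of
#' exposed samples, a uniform exposure, and a normal exposure.
#'
#' For binary exposures the two categories can either be coded `1` (exposed)
#' and `0` (unexposed), or — when `encode_variance_only = TRUE` — with the
#' variance-only coding returned by [binary_exposure_encoding()], which fixes
#' the unexposed category at `-1` and chooses the exposed code so that the
#' population mean of the exposure is zero. Under that coding a pure
#' genotype-by-exposure interaction changes the trait variance across
#' genotype groups without shifting their means, which is what defines a
#' variance-only vQTL scenario.
#'
#' @param kind one of `"binary"`, `"uniform"`, `"normal"`.
#' @param f_E fraction of exposed samples (binary only), strictly inside
#'   (0, 1). Default `0.1`.
#' @param low,high bounds of the uniform exposure. Defaults 20 and 70.
#' @param mu,sd mean and standard deviation of the normal exposure.
#'   Defaults 25 and 3.
#' @param encode_variance_only logical; use the mean-zero variance-only
#'   coding for binary exposures (default `TRUE`). Ignored for continuous
#'   exposures.
#' @return An object of class `"exposure_spec"`.
#' @examples
#' exposure_spec("binary", f_E = 0.1)
#' exposure_spec("uniform")
#' @seealso [binary_exposure_encoding()], [simulate_exposure()]
#' @export
exposure_spec <- function(kind = c("binary", "uniform", "normal"),
                          f_E = 0.1, low = 20, high = 70,
                          mu = 25, sd = 3,
                          encode_variance_only = TRUE) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    check_scalar_number(f_E, "f_E")
    if (f_E <= 0 || f_E >= 1)
      stopf("binary exposure needs 0 < f_E < 1, got %g", f_E)
  } else if (kind == "uniform") {
    check_scalar_number(low, "low"); check_scalar_number(high, "high")
    if (low >= high) stopf("uniform exposure needs low < high")
  } else {
    check_scalar_number(mu, "mu"); check_scalar_number(sd, "sd")
    if (sd <= 0) stopf("normal exposure needs sd > 0")
  }
  structure(
    list(kind = kind, f_E = f_E, low = low, high = high, mu = mu, sd = sd,
         encode_variance_only = isTRUE(encode_variance_only) &&
           kind == "binary"),
    class = "exposure_spec")
}

#' Describe the error (noise) distribution of a simulated cohort
#'
#' @param kind one of `"normal"`, `"chisq"`, `"gamma"`.
#' @param df degrees of freedom of the chi-squared error (default 1).
#' @param shape1,shape2 shape and rate of the gamma error (defaults 2 and
#'   0.5).
#' @return An object of class `"error_spec"`.
#' @examples
#' error_spec("chisq", df = 1)
#' error_spec("gamma")
#' @export
error_spec <- function(kind = c("normal", "chisq", "gamma"),
                       df = 1, shape1 = 2, shape2 = 0.5) {
  kind <- match.arg(kind)
  if (kind == "chisq") {
    check_scalar_number(df, "df")
    if (df <= 0) stopf("chi-squared error needs df > 0")
  }
  if (kind == "gamma") {
    check_scalar_number(shape1, "shape1"); check_scalar_number(shape2, "shape2")
    if (shape1 <= 0 || shape2 <= 0) stopf("gamma error needs positive shapes")
  }
  structure(list(kind = kind, df = df, shape1 = shape1, shape2 = shape2),
            class = "error_spec")
}

draw_error <- function(spec, n) {
  switch(spec$kind,
         normal = rnorm(n),
         chisq  = rchisq(n, df = spec$df),
         gamma  = rgamma(n, shape = spec$shape1, rate = spec$shape2))
}

#' Full parameterization of one simulated generative setting
#'
#' A scenario bundles everything needed to draw one cohort under the
#' additive + environment + interaction + error trait model: the sample
#' size, the minor allele frequency of the single biallelic locus, the four
#' component weights, the exposure and error distributions, and the seed.
#' The weights must sum to one; `a_E` is therefore derived as
#' `1 - a_mean - a_var - a_error` and must be non-negative.
#'
#' @param n sample size (at least `3 * min_group`).
#' @param maf minor allele frequency, in (0, 0.5].
#' @param a_mean weight of the additive genetic component.
#' @param a_var weight of the genotype-by-exposure interaction component.
#' @param a_error weight of the error component (default 0.2).
#' @param exposure an [exposure_spec()].
#' @param error an [error_spec()].
#' @param genetic_exposure logical; replace the exposure `E` by the
#'   genetically associated exposure `E1 = E + a_mean * G` (raw scales).
#' @param interact which allele's dosage enters the trait model: the
#'   `"major"` (common) allele — the default, i.e. dosage `2 - g` when `g`
#'   counts minor alleles — or the `"minor"` allele (dosage `g`).
#' @param min_group minimum number of samples per genotype group
#'   (default 10).
#' @param sampling genotype-group size policy, see [simulate_genotypes()].
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `"simulation_scenario"`, a list with the
#'   above fields plus the derived weight `a_E`.
#' @examples
#' sc <- simulation_scenario(n = 1000, maf = 0.05, a_mean = 0, a_var = 0.1)
#' sc$a_E
#' @export
simulation_scenario <- function(n, maf, a_mean = 0, a_var = 0,
                                a_error = 0.2,
                                exposure = exposure_spec("binary"),
                                error = error_spec("normal"),
                                genetic_exposure = FALSE,
                                interact = c("major", "minor"),
                                min_group = 10,
                                sampling = c("fixed", "multinomial"),
                                seed = 1L) {
  check_scalar_number(n, "n"); check_scalar_number(maf, "maf")
  check_scalar_number(a_mean, "a_mean"); check_scalar_number(a_var, "a_var")
  check_scalar_number(a_error, "a_error")
  interact <- match.arg(interact)
  sampling <- match.arg(sampling)
  if (!inherits(exposure, "exposure_spec"))
    stopf("'exposure' must be built with exposure_spec()")
  if (!inherits(error, "error_spec"))
    stopf("'error' must be built with error_spec()")
  if (a_mean < 0 || a_var < 0 || a_error < 0)
    stopf("component weights must be non-negative")
  a_E <- 1 - a_mean - a_var - a_error
  if (a_E < -1e-12)
    stopf("weights exceed 1: a_E = 1 - a_mean - a_var - a_error = %g < 0", a_E)
  a_E <- max(a_E, 0)
  if (maf <= 0 || maf > 0.5) stopf("'maf' must lie in (0, 0.5], got %g", maf)
  if (n < 3 * min_group)
    stopf("n = %d cannot hold three genotype groups of at least %d samples",
          as.integer(n), as.integer(min_group))
  structure(
    list(n = as.integer(n), maf = maf, a_mean = a_mean, a_E = a_E,
         a_var = a_var, a_error = a_error, exposure = exposure,
         error = error, genetic_exposure = isTRUE(genetic_exposure),
         interact = interact, min_group = as.integer(min_group),
         sampling = sampling, seed = as.integer(seed)),
    class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "vQTL simulation scenario: n=%d, MAF=%.3g\n  weights: a_mean=%.3g, a_E=%.3g, a_var=%.3g, a_error=%.3g\n  exposure: %s, error: %s%s, seed=%d\n",
    x$n, x$maf, x$a_mean, x$a_E, x$a_var, x$a_error,
    x$exposure$kind, x$error$kind,
    if (x$genetic_exposure) ", genetically associated exposure" else "",
    x$seed))
  invisible(x)
}
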