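#' Variance-only coding of a binary exposure
#'
#' In a pure genotype-by-exposure interaction model the trait mean of a
#' genotype group with interacting-allele dosage `d` is proportional to
#' `d * sum(E_i * f_i)` over exposure categories `i` with codes `E_i` and
#' frequencies `f_i`. Coding the two categories so that this weighted mean
#' is zero removes the mean shift entirely, leaving a variance-only signal.
#' With the unexposed category fixed at `-1`, the exposed code solving
#' `f_E * x + (1 - f_E) * (-1) = 0` is `(1 - f_E) / f_E`: 9 for a 10%/90%
#' split, 1 for a balanced 50%/50% split.
#'
#' @param f_E fraction of exposed samples, strictly inside (0, 1).
#' @return A named numeric vector `c(x_exposed =, x_unexposed = -1)`.
#' @examples
#' binary_exposure_encoding(0.1)  # c(9, -1)
#' binary_exposure_encoding(0.5)  # c(1, -1)
#' @export
binary_exposure_encoding <- function(f_E) {
  check_scalar_number(f_E, "f_E")
  if (f_E <= 0 || f_E >= 1)
    stopf("'f_E' must lie strictly inside (0, 1), got %g", f_E)
  c(x_exposed = (1 - f_E) / f_E, x_unexposed = -1)
}

#' Simulate the environmental exposure of a cohort
#'
#' Binary exposures assign exactly `round(f_E * n)` samples to the exposed
#' category (in randomized order), so the stated category proportions hold
#' exactly within every replicate; the codes are the variance-only coding
#' of [binary_exposure_encoding()] when `spec$encode_variance_only` is set,
#' and 1/0 otherwise. Continuous exposures are i.i.d. draws from the stated
#' uniform or normal distribution; their category proportions are not
#' controlled. When `genetic_exposure` is `TRUE` the returned vector is the
#' genetically associated exposure `E1 = E + a_mean * G`, computed on raw
#' (pre-normalization) scales with `G` the interacting-allele dosage.
#'
#' @param spec an [exposure_spec()].
#' @param n sample size.
#' @param g genotype dosage vector of length `n` used only for the
#'   genetically associated variant (pass the interacting-allele dosage).
#' @param a_mean additive weight used in `E1 = E + a_mean * G`.
#' @param genetic_exposure logical.
#' @param seed optional integer seed.
#' @return Numeric exposure vector of length `n`.
#' @examples
#' e <- simulate_exposure(exposure_spec("binary", f_E = 0.1), 1000, seed = 1)
#' table(e)  # 100 samples at 9, 900 at -1
#' @export
simulate_exposure <- function(spec, n, g = NULL, a_mean = 0,
                              genetic_exposure = FALSE, seed = NULL) {
  if (!inherits(spec, "exposure_spec"))
    stopf("'spec' must be built with exposure_spec()")
  check_scalar_number(n, "n"); n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  e <- switch(spec$kind,
    binary = {
      n_exposed <- as.integer(round(spec$f_E * n))
      if (n_exposed < 1L || n_exposed > n - 1L)
        stopf("f_E = %g leaves an empty exposure category at n = %d",
              spec$f_E, n)
      codes <- if (spec$encode_variance_only)
        binary_exposure_encoding(spec$f_E) else c(1, 0)
      sample(rep(c(codes[[1]], codes[[2]]), c(n_exposed, n - n_exposed)))
    },
    uniform = runif(n, spec$low, spec$high),
    normal  = rnorm(n, spec$mu, spec$sd))
  if (isTRUE(genetic_exposure) && a_mean != 0) {
    if (is.null(g) || length(g) != n)
      stopf("the genetically associated exposure needs a genotype vector of length n")
    e <- e + a_mean * g
  }
  e
}
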