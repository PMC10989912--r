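#' Preprocessing plan applied before vQTL testing
#'
#' Captures the three preprocessing switches the benchmark varies:
#' whether the exposure is regressed out of the trait (`adjust_exposure`,
#' the observed-exposure protocol; `FALSE` reproduces the
#' unobserved-exposure variant where the raw trait enters the tests),
#' whether the genotype is additionally regressed out (`adjust_genotype`,
#' the SVLM/CLS route — those two methods adjust on both exposure and
#' genotype), and whether the residuals are rank inverse-normal
#' transformed before testing (`apply_int`, the normalization experiment).
#' The Z-score test transforms internally and is never combined with
#' `apply_int`; the dispatcher skips the INT step for it.
#'
#' @param adjust_exposure logical, default `TRUE`.
#' @param adjust_genotype logical, default `FALSE`. [run_method()] forces
#'   it for SVLM and CLS.
#' @param apply_int logical, default `FALSE`.
#' @param int_offset rank offset convention for the INT, `"half"` for
#'   `(rank - 0.5)/n` (default) or `"blom"` for
#'   `(rank - 3/8)/(n + 1/4)`.
#' @return An object of class `"preprocess_plan"`.
#' @examples
#' preprocess_plan()                       # observed exposure, no INT
#' preprocess_plan(adjust_exposure = FALSE) # unobserved-exposure variant
#' @export
preprocess_plan <- function(adjust_exposure = TRUE, adjust_genotype = FALSE,
                            apply_int = FALSE,
                            int_offset = c("half", "blom")) {
  structure(list(adjust_exposure = isTRUE(adjust_exposure),
                 adjust_genotype = isTRUE(adjust_genotype),
                 apply_int = isTRUE(apply_int),
                 int_offset = match.arg(int_offset)),
            class = "preprocess_plan")
}

#' Residualize a trait on covariates by ordinary least squares
#'
#' Returns OLS residuals of `y` on an intercept plus the supplied
#' covariates (plus the genotype when given). With no covariates this is
#' mean-centering. Residuals are exactly orthogonal to every regressor.
#' A rank-deficient design raises an error naming the collinear column.
#'
#' @param y numeric trait vector.
#' @param covariates `NULL`, a numeric vector, matrix or data.frame with
#'   one row per sample.
#' @param g optional genotype vector appended as a regressor.
#' @return Numeric residual vector of length `length(y)`.
#' @examples
#' e <- rnorm(50)
#' y <- 2 * e + rnorm(50)
#' r <- adjust_covariates(y, e)
#' abs(sum(r * e)) < 1e-8
#' @export
adjust_covariates <- function(y, covariates = NULL, g = NULL) {
  if (!is.numeric(y)) stopf("'y' must be numeric")
  n <- length(y)
  X <- as_covariate_matrix(covariates, n)
  if (!is.null(g)) {
    if (length(g) != n) stopf("'g' must have length %d", n)
    X <- cbind(X, genotype = as.numeric(g))
  }
  X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("rank-deficient adjustment design: column(s) %s are collinear",
          paste(dropped, collapse = ", "))
  }
  unname(qr.resid(qx, y))
}

#' Rank-based inverse normal transformation
#'
#' Maps values through `qnorm((rank - 0.5) / n)` (or the Blom offset
#' `(rank - 3/8)/(n + 1/4)`), with average ranks for ties, producing
#' approximate standard-normal scores. Strictly monotone on untied input
#' and antisymmetric: `rank_int(-y) == -rank_int(y)` when `y` is untied.
#'
#' @param y numeric vector, length at least 3, not all values identical.
#' @param offset `"half"` (default) or `"blom"`.
#' @return Numeric vector of normal scores.
#' @examples
#' rank_int(c(5, 1, 3))
#' @export
rank_int <- function(y, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  if (!is.numeric(y) || length(y) < 3L)
    stopf("'y' must be a numeric vector of length >= 3")
  if (anyNA(y)) stopf("missing values in 'y'")
  if (min(y) == max(y))
    stopf("all values of 'y' are identical: ranks carry no ordering information")
  n <- length(y)
  r <- rank(y, ties.method = "average")
  p <- if (offset == "half") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
  qnorm(p)
}
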