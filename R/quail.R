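# Quantile integral linear model (QUAIL).

#' Quantile integral linear model test (QUAIL)
#'
#' QUAIL summarizes genotype effects across the whole outcome distribution
#' by quantile regression. For quantile levels `tau_k = k / (n_quantiles + 1)`
#' the genotype's quantile-regression slopes `beta_tau` are combined into
#' the integrated variance effect
#' `beta = integral over (0, 0.5) of (beta_{1 - tau} - beta_tau) d tau`,
#' approximated by the Riemann sum of `beta_{1 - tau} - beta_tau` over the
#' grid levels below one half with step `1 / (n_quantiles + 1)`. A variant widening the upper quantiles relative
#' to the lower ones yields a positive `beta`.
#'
#' Significance uses an integrated rank-score construction: the trait is
#' first residualized on the covariates, each sample receives the quantile
#' rank score `a_tau(i) = tau - 1(y_i < q_tau)` built from the null
#' (intercept-only) quantile fits, the scores are integrated over the same
#' grid as `psi_i = mean over tau < 0.5 of (a_{1 - tau}(i) - a_tau(i))`,
#' and `psi` is regressed on the genotype with a two-sided t-test. Because
#' `psi` depends on the trait only through ranks, the test is calibrated
#' under any exchangeable null. A genotype-permutation fallback
#' (`inference = "permutation"`) re-draws the slope of `psi` on permuted
#' genotypes instead of using the t reference.
#'
#' The integrated effect size is fitted with [quantreg::rq()] at all grid
#' levels when `estimate_beta = TRUE`; with `estimate_beta = FALSE` the
#' (much cheaper) slope of the integrated rank score is reported instead,
#' which has the same sign and null behaviour but a different scale.
#'
#' @param y numeric trait vector.
#' @param g genotype vector coded 0/1/2.
#' @param covariates optional covariates, residualized out before the
#'   quantile machinery.
#' @param n_quantiles even number of grid levels (default 100).
#' @param inference `"rank_score"` (default) or `"permutation"`.
#' @param n_perm permutations for the fallback (default 200).
#' @param estimate_beta logical; fit the per-quantile slopes to report the
#'   integrated effect size (default `TRUE`).
#' @return A `vqtl_test` result; `converged = FALSE` with the failing
#'   quantile level in the note if a quantile fit fails.
#' @examples
#' set.seed(1)
#' g <- rep(0:2, each = 40)
#' y <- g * runif(120, -1, 1)
#' quail_test(y, g, n_quantiles = 20)
#' @export
quail_test <- function(y, g, covariates = NULL, n_quantiles = 100,
                       inference = c("rank_score", "permutation"),
                       n_perm = 200, estimate_beta = TRUE) {
  inference <- match.arg(inference)
  check_yg(y, g)
  check_scalar_number(n_quantiles, "n_quantiles")
  if (n_quantiles < 2 || n_quantiles %% 2 != 0)
    stopf("'n_quantiles' must be a positive even number, got %g", n_quantiles)
  n <- length(y)
  n_reg <- 2L + ncol(as_covariate_matrix(covariates, n))
  if (n < 50 * n_reg)
    stopf("QUAIL needs n >= 50 regressors; n = %d with %d regressors", n, n_reg)

  y_adj <- if (is.null(covariates)) y else adjust_covariates(y, covariates)
  taus <- seq_len(n_quantiles) / (n_quantiles + 1)
  lower <- taus[taus < 0.5]

  # Integrated rank score from the null (intercept-only) quantile fits:
  # the tau-quantile of y_adj. psi is a V-shaped function of the rank.
  q_lo <- quantile(y_adj, probs = lower, type = 1, names = FALSE)
  q_hi <- quantile(y_adj, probs = 1 - lower, type = 1, names = FALSE)
  ind_lo <- colMeans(outer(q_lo, y_adj, `>`))   # mean_tau 1{y < q_tau}
  ind_hi <- colMeans(outer(q_hi, y_adj, `>`))
  psi <- mean(1 - 2 * lower) - ind_hi + ind_lo

  fit <- ols_slope_test(psi, as.numeric(g))
  if (inference == "permutation") {
    if (n_perm < 1) stopf("'n_perm' must be at least 1")
    obs <- abs(fit$slope)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(g)
      xc <- gp - mean(gp)
      slope_b <- sum(xc * (psi - mean(psi))) / sum(xc^2)
      if (abs(slope_b) >= obs) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  } else {
    p_value <- fit$p
  }

  effect <- fit$slope
  converged <- TRUE; note <- NULL
  if (isTRUE(estimate_beta)) {
    beta <- tryCatch(
      {
        rqfit <- suppressWarnings(
          quantreg::rq.fit.br(cbind(1, as.numeric(g)), y_adj, tau = -1))
        beta_at <- function(tau) {
          # coefficient path from the full br solution
          idx <- findInterval(tau, rqfit$sol["tau", ], rightmost.closed = TRUE)
          rqfit$sol[5L, pmax(idx, 1L)]
        }
        # Riemann sum of the integral over (0, 0.5), step 1/(K + 1)
        sum(beta_at(1 - lower) - beta_at(lower)) / (n_quantiles + 1)
      },
      error = function(e) e)
    if (inherits(beta, "error")) {
      # retry tau by tau so the failing level can be reported
      betas <- rep(NA_real_, length(taus))
      for (k in seq_along(taus)) {
        bk <- tryCatch(suppressWarnings(
          quantreg::rq.fit(cbind(1, as.numeric(g)), y_adj,
                           tau = taus[k])$coefficients[2L]),
          error = function(e) NA_real_)
        betas[k] <- bk
      }
      if (anyNA(betas)) {
        failed <- taus[which(is.na(betas))[1L]]
        converged <- FALSE
        note <- sprintf("quantile fit failed at tau = %.3g", failed)
      } else {
        half <- length(lower)
        beta <- sum(betas[n_quantiles + 1 - seq_len(half)] -
                      betas[seq_len(half)]) / (n_quantiles + 1)
      }
    }
    if (converged) effect <- beta
  }

  new_test_result("quail", statistic = fit$t, p_value = p_value,
                  effect_size = if (converged) effect else NA_real_,
                  df = fit$df, converged = converged, note = note)
}
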