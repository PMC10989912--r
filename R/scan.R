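# Matrix-scale vQTL scanning with permutation-based FDR and the epistasis
# interaction check.

#' Read a genotype matrix from a 0/1/2 TSV or a VCF
#'
#' The TSV dialect has variants in rows, samples in columns, a header row
#' of sample ids and the variant id in the first column. The VCF dialect
#' extracts diploid GT fields and codes each variant as the count of the
#' alternate allele; samples with missing genotypes get `NA` (dropped per
#' variant during scanning). Coordinates are irrelevant to the statistics
#' and are kept only in the variant ids.
#'
#' @param path file path (`.vcf` or tab-separated text).
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return Numeric matrix, variants x samples, dimnames set.
#' @export
read_genotype_matrix <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stopf("reading VCF needs the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- apply(gt, c(1, 2), function(x) {
      if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.numeric(strsplit(x, "[/|]")[[1]]) > 0)
    })
    ids <- v@fix[, "ID"]
    miss <- is.na(ids) | ids == "."
    ids[miss] <- paste0(v@fix[miss, "CHROM"], ":", v@fix[miss, "POS"])
    rownames(counts) <- ids
    return(counts)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  m
}

filter_variants <- function(genotypes, maf_min, min_group) {
  keep <- logical(nrow(genotypes))
  reason <- character(nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    g <- g[!is.na(g)]
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    counts <- tabulate(g + 1L, 3L)
    if (maf < maf_min) {
      reason[i] <- sprintf("maf %.4g < %.4g", maf, maf_min)
    } else if (any(counts < min_group)) {
      reason[i] <- sprintf("min_group: genotype class %d has %d < %d samples",
                           which(counts < min_group)[1L] - 1L,
                           min(counts), min_group)
    } else keep[i] <- TRUE
  }
  list(keep = keep, reason = reason)
}

#' Scan a phenotype matrix against a genotype matrix for vQTLs
#'
#' Runs the chosen vQTL tests on every (feature, variant) pair. Variants
#' are first filtered to a minimum minor allele frequency and a minimum
#' count per genotype class (the same guard the simulations apply);
#' skipped variants are reported with reasons in the `"skipped"`
#' attribute.
#'
#' @param phenotypes numeric matrix, features x samples (column names are
#'   sample ids).
#' @param genotypes numeric matrix, variants x samples, coded 0/1/2.
#' @param covariates optional per-sample covariates (rows = samples).
#' @param methods method names, default `c("bf", "svlm", "drm")` (the
#'   best-calibrated trio).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param min_group minimum samples per genotype class (default 10).
#' @param plan a [preprocess_plan()]; default adjusts on the covariates
#'   only when some are supplied.
#' @return A data.frame of class `"scan_result"`: `feature`, `variant`,
#'   `method`, `statistic`, `p_value`, `effect_size`, `converged`.
#' @export
vqtl_scan <- function(phenotypes, genotypes, covariates = NULL,
                      methods = c("bf", "svlm", "drm"),
                      maf_min = 0.05, min_group = 10,
                      plan = NULL) {
  if (!is.matrix(phenotypes) || !is.matrix(genotypes))
    stopf("'phenotypes' and 'genotypes' must be matrices (features/variants x samples)")
  if (is.null(colnames(phenotypes)) || is.null(colnames(genotypes)))
    stopf("both matrices need sample ids as column names")
  if (!identical(sort(colnames(phenotypes)), sort(colnames(genotypes))))
    stopf("sample ids of the phenotype and genotype matrices do not match")
  genotypes <- genotypes[, colnames(phenotypes), drop = FALSE]
  if (is.null(plan))
    plan <- preprocess_plan(adjust_exposure = !is.null(covariates))
  flt <- filter_variants(genotypes, maf_min, min_group)
  skipped <- data.frame(variant = rownames(genotypes)[!flt$keep],
                        reason = flt$reason[!flt$keep],
                        stringsAsFactors = FALSE)
  if (!any(flt$keep))
    stopf("no variant passes the MAF/min_group filters")
  kept <- which(flt$keep)
  rows <- vector("list", nrow(phenotypes) * length(kept))
  k <- 0L
  for (fi in seq_len(nrow(phenotypes))) {
    y_all <- phenotypes[fi, ]
    for (vi in kept) {
      g <- genotypes[vi, ]
      use <- !is.na(g) & !is.na(y_all)
      res <- run_methods(y_all[use], g[use],
                         covariates = if (is.null(covariates)) NULL else
                           covariates[use, , drop = FALSE],
                         methods = methods, plan = plan)
      res <- cbind(feature = rownames(phenotypes)[fi],
                   variant = rownames(genotypes)[vi], res,
                   stringsAsFactors = FALSE)
      k <- k + 1L
      rows[[k]] <- res
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "skipped") <- skipped
  class(out) <- c("scan_result", class(out))
  out
}

#' Permutation-based false discovery rate for a scan
#'
#' Estimates the FDR at each observed p-value threshold by re-running the
#' scan on data with phenotype sample labels permuted against the whole
#' genotype set (preserving linkage among variants), as
#' `FDR(t) = mean permuted count of p <= t / observed count of p <= t`,
#' clipped to `[0, 1]` and made monotone non-decreasing in `p` by a
#' step-up pass (so the estimate never decreases as the threshold
#' loosens).
#'
#' @param observed_p observed p-value vector.
#' @param y phenotype vector the p-values came from.
#' @param genotypes variant x sample genotype matrix used in the scan.
#' @param method one method name.
#' @param covariates optional covariates (permuted together with `y`).
#' @param n_perm number of permutations (default 20).
#' @param plan a [preprocess_plan()].
#' @param seed integer seed for the permutations.
#' @return Numeric FDR vector aligned with `observed_p`.
#' @export
permutation_fdr <- function(observed_p, y, genotypes, method,
                            covariates = NULL, n_perm = 20,
                            plan = NULL, seed = 1L) {
  if (n_perm < 1) stopf("'n_perm' must be at least 1")
  if (!length(observed_p)) stopf("'observed_p' is empty")
  if (is.null(plan))
    plan <- preprocess_plan(adjust_exposure = !is.null(covariates))
  set.seed(seed)
  n <- length(y)
  perm_p <- matrix(NA_real_, nrow = n_perm, ncol = nrow(genotypes))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    yp <- y[idx]
    cp <- if (is.null(covariates)) NULL else covariates[idx, , drop = FALSE]
    for (vi in seq_len(nrow(genotypes))) {
      res <- run_method(method, yp, genotypes[vi, ], covariates = cp,
                        plan = plan)
      perm_p[b, vi] <- res$p_value
    }
  }
  ord <- order(observed_p)
  fdr <- numeric(length(observed_p))
  for (i in seq_along(observed_p)) {
    t <- observed_p[i]
    n_obs <- sum(observed_p <= t)
    n_perm_hits <- mean(rowSums(perm_p <= t, na.rm = TRUE))
    fdr[i] <- if (n_obs == 0) 1 else min(n_perm_hits / n_obs, 1)
  }
  # step-up: running minimum from the largest p downward makes the
  # estimate monotone non-decreasing in p
  fdr[ord] <- rev(cummin(rev(fdr[ord])))
  fdr
}

#' Epistasis interaction check between a vQTL and a candidate partner
#'
#' A detected vQTL can arise from an epistatic interaction between two
#' loci. This check fits the linear model
#' `y ~ g1 + g2 + g1:g2 (+ covariates)` and reports the two-sided Wald
#' test of the product term; the product coefficient is the effect size.
#'
#' @param y numeric trait vector.
#' @param g1,g2 genotype vectors coded 0/1/2.
#' @param covariates optional covariates.
#' @return A `vqtl_test` result for the interaction term.
#' @export
epistasis_interaction_test <- function(y, g1, g2, covariates = NULL) {
  check_yg(y, g1); check_yg(y, g2)
  X <- cbind(`(Intercept)` = 1, g1 = as.numeric(g1), g2 = as.numeric(g2),
             `g1:g2` = as.numeric(g1) * as.numeric(g2),
             as_covariate_matrix(covariates, length(y)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stopf("collinear interaction design (e.g. perfect LD or a constant variant): %s",
          paste(dropped, collapse = ", "))
  }
  cf <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  Rinv <- backsolve(qr.R(qx), diag(ncol(X)))
  cov_beta <- sigma2 * tcrossprod(Rinv)
  pos <- match("g1:g2", colnames(X))
  # account for qr pivoting
  pivpos <- match(pos, qx$pivot)
  se <- sqrt(cov_beta[pivpos, pivpos])
  tval <- cf[pos] / se
  new_test_result("epistasis", statistic = tval,
                  p_value = 2 * pt(abs(tval), df, lower.tail = FALSE),
                  effect_size = unname(cf[pos]), df = df)
}
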