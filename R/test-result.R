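# Common container for all vQTL method outputs.

new_test_result <- function(method, statistic, p_value, effect_size = NA_real_,
                            df = NA_real_, converged = TRUE, note = NULL) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stopf("internal error: p-value %g outside [0, 1]", p_value)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 effect_size = effect_size, df = df,
                 converged = isTRUE(converged), note = note),
            class = "vqtl_test")
}

#' @export
print.vqtl_test <- function(x, ...) {
  cat(sprintf("vQTL test [%s]: statistic = %.6g, p = %.4g%s%s%s\n",
              x$method, x$statistic, x$p_value,
              if (!is.na(x$effect_size))
                sprintf(", effect size = %.6g", x$effect_size) else "",
              if (!x$converged) " (NOT converged)" else "",
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.vqtl_test <- function(x, ...) {
  data.frame(method = x$method, statistic = x$statistic, p_value = x$p_value,
             effect_size = x$effect_size, df = x$df, converged = x$converged,
             stringsAsFactors = FALSE)
}

# Genotype groups as a factor with informative checks shared by the
# group-based tests.
genotype_groups <- function(y, g, min_per_group = 2L) {
  check_yg(y, g)
  f <- factor(g)
  if (nlevels(f) < 2L)
    stopf("all samples fall in a single genotype group; a variance comparison needs at least two")
  sizes <- tabulate(f)
  if (any(sizes < min_per_group))
    stopf("genotype group '%s' has fewer than %d samples",
          levels(f)[which(sizes < min_per_group)[1L]], min_per_group)
  f
}
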