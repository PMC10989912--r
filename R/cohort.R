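#' Min-max normalization to the unit interval
#'
#' Rescales a vector to `[0, 1]` by `(v - min(v)) / (max(v) - min(v))`.
#' The map is invariant to positive affine transformations of the input.
#' A constant vector carries no scale information and maps to all zeros
#' (rather than erroring), so scenarios with a zero weight on a component
#' degrade gracefully; this convention is deliberate and documented.
#'
#' @param v numeric vector of length at least 1.
#' @return Numeric vector of the same length, in `[0, 1]`.
#' @examples
#' minmax(c(0, 5, 10))
#' minmax(c(3, 3, 3))  # constant maps to zeros
#' @export
minmax <- function(v) {
  if (!is.numeric(v) || length(v) < 1L)
    stopf("'v' must be a non-empty numeric vector")
  if (anyNA(v)) stopf("missing values in 'v'")
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' Simulate one cohort under the gene-by-environment trait model
#'
#' Draws genotypes, exposure and error for a [simulation_scenario()] and
#' assembles the quantitative trait
#' `y = a_mean * G + a_E * E + a_var * GxE + a_error * error`,
#' where each of the four component vectors (interacting-allele dosage,
#' encoded exposure, their elementwise product, and the error draw) is
#' min-max normalized to `[0, 1]` *before* weighting. The interaction term
#' is the product of the raw dosage and the raw encoded exposure,
#' normalized after multiplication. By default the interacting allele is
#' the common (major) allele, so the dosage entering the model is `2 - g`
#' with `g` the stored minor-allele count; `interact = "minor"` flips this.
#'
#' @param scenario a [simulation_scenario()].
#' @return An object of class `"simulated_cohort"`: a list with the trait
#'   `y`, minor-allele genotype codes `g` (0/1/2), the raw-scale exposure
#'   `e_raw`, the four normalized component vectors in `terms`
#'   (`G`, `E`, `GxE`, `error`), and the generating `scenario`.
#' @examples
#' sc <- simulation_scenario(n = 500, maf = 0.2, a_var = 0.1, seed = 7)
#' cohort <- simulate_trait(sc)
#' range(cohort$terms$GxE)
#' @export
simulate_trait <- function(scenario) {
  if (!inherits(scenario, "simulation_scenario"))
    stopf("'scenario' must be built with simulation_scenario()")
  set.seed(scenario$seed)
  g <- simulate_genotypes(scenario$n, scenario$maf,
                          min_group = scenario$min_group,
                          sampling = scenario$sampling)
  dosage <- if (scenario$interact == "major") 2L - g else g
  e_raw <- simulate_exposure(scenario$exposure, scenario$n, g = dosage,
                             a_mean = scenario$a_mean,
                             genetic_exposure = scenario$genetic_exposure)
  err <- draw_error(scenario$error, scenario$n)
  terms <- list(G = minmax(dosage), E = minmax(e_raw),
                GxE = minmax(dosage * e_raw), error = minmax(err))
  y <- scenario$a_mean * terms$G + scenario$a_E * terms$E +
    scenario$a_var * terms$GxE + scenario$a_error * terms$error
  structure(list(y = y, g = g, e_raw = e_raw, terms = terms,
                 scenario = scenario),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: n=%d, genotype counts %s\n",
              length(x$y), paste(tabulate(x$g + 1L, 3L), collapse = "/")))
  print(x$scenario)
  invisible(x)
}

#' Export a simulated cohort as TSV
#'
#' Writes columns `sample_id`, `y`, `g`, `e_raw` with a header row.
#'
#' @param cohort a [simulate_trait()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  if (!inherits(cohort, "simulated_cohort"))
    stopf("'cohort' must be a simulated_cohort")
  df <- data.frame(sample_id = sprintf("S%06d", seq_along(cohort$y)),
                   y = cohort$y, g = cohort$g, e_raw = cohort$e_raw)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a scenario grid from a configuration list or YAML file
#'
#' The configuration holds vectors for the grid axes (`n`, `maf`, `a_mean`,
#' `a_var`, `f_E`, plus `exposure_kind`, `error_kind`) and scalars for the
#' rest; every combination becomes one [simulation_scenario()]. Axis
#' defaults are the benchmark grids: `n` in 500...200,000, `maf` in
#' {0.05, 0.1, 0.2, 0.3}, `f_E` in {0.1, 0.3, 0.5} and weights in
#' {0, 0.005, ..., 0.4}; a configuration normally restricts them.
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return A list of `simulation_scenario` objects; names are compact
#'   scenario ids.
#' @examples
#' grid <- scenario_grid(list(n = c(500, 1000), maf = 0.05,
#'                            a_mean = 0, a_var = c(0, 0.1)))
#' length(grid)
#' @export
scenario_grid <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("'config' must be a list or a YAML file path")
  defaults <- list(
    n = c(500, 1000, 5000, 10000, 20000, 50000, 100000, 200000),
    maf = c(0.05, 0.1, 0.2, 0.3),
    a_mean = c(0, 0.005, 0.01, 0.03, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4),
    a_var  = c(0, 0.005, 0.01, 0.03, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4),
    a_error = 0.2, f_E = 0.1, exposure_kind = "binary", error_kind = "normal",
    encode_variance_only = TRUE, genetic_exposure = FALSE,
    interact = "major", min_group = 10, sampling = "fixed", seed = 1L,
    chisq_df = 1, gamma_shape1 = 2, gamma_shape2 = 0.5,
    uniform_low = 20, uniform_high = 70, normal_mu = 25, normal_sd = 3)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  axes <- expand.grid(n = cfg$n, maf = cfg$maf, a_mean = cfg$a_mean,
                      a_var = cfg$a_var, f_E = cfg$f_E,
                      exposure_kind = cfg$exposure_kind,
                      error_kind = cfg$error_kind,
                      stringsAsFactors = FALSE)
  # drop weight combinations exceeding the unit budget
  keep <- axes$a_mean + axes$a_var + cfg$a_error <= 1 + 1e-12
  axes <- axes[keep, , drop = FALSE]
  if (nrow(axes) == 0L) stopf("no feasible scenario in the grid")
  scenarios <- vector("list", nrow(axes))
  for (i in seq_len(nrow(axes))) {
    row <- axes[i, ]
    scenarios[[i]] <- simulation_scenario(
      n = row$n, maf = row$maf, a_mean = row$a_mean, a_var = row$a_var,
      a_error = cfg$a_error,
      exposure = exposure_spec(row$exposure_kind, f_E = row$f_E,
                               low = cfg$uniform_low, high = cfg$uniform_high,
                               mu = cfg$normal_mu, sd = cfg$normal_sd,
                               encode_variance_only = cfg$encode_variance_only),
      error = error_spec(row$error_kind, df = cfg$chisq_df,
                         shape1 = cfg$gamma_shape1, shape2 = cfg$gamma_shape2),
      genetic_exposure = cfg$genetic_exposure, interact = cfg$interact,
      min_group = cfg$min_group, sampling = cfg$sampling, seed = cfg$seed)
  }
  names(scenarios) <- sprintf(
    "n%g_maf%g_am%g_av%g_%s_%s%s", axes$n, axes$maf, axes$a_mean, axes$a_var,
    axes$exposure_kind, axes$error_kind,
    ifelse(axes$exposure_kind == "binary", sprintf("_fE%g", axes$f_E), ""))
  scenarios
}
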