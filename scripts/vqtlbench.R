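#!/usr/bin/env Rscript
# Thin command-line front end over the vqtlbench package.
#
#   Rscript scripts/vqtlbench.R grid --config grid.yaml --out results.tsv \
#       --seed 1 [--methods bf,svlm,drm] [--reps 1000] [--alpha 0.05]
#
# The YAML config holds scenario-grid axes (see ?scenario_grid).

suppressPackageStartupMessages(library(vqtlbench))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L || args[1] != "grid") {
  cat("usage: vqtlbench.R grid --config <yaml> --out <tsv> --seed <int>",
      "[--methods m1,m2] [--reps N] [--alpha a] [--no-adjust] [--int]\n")
  quit(status = if (length(args)) 1L else 0L)
}
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
config <- opt("--config")
out <- opt("--out", "results.tsv")
seed <- as.integer(opt("--seed", "1"))
methods <- strsplit(opt("--methods", "bf,svlm,drm"), ",")[[1]]
reps <- as.integer(opt("--reps", "1000"))
alpha <- as.numeric(opt("--alpha", "0.05"))
plan <- preprocess_plan(adjust_exposure = !("--no-adjust" %in% args),
                        apply_int = "--int" %in% args)
if (is.null(config)) stop("--config is required", call. = FALSE)

scenarios <- scenario_grid(config)
message(length(scenarios), " scenarios x ", length(methods), " methods x ",
        reps, " replicates")
tab <- run_grid(scenarios, methods = methods, n_reps = reps, alpha = alpha,
                plan = plan, seed = seed)
write_results_tsv(tab[, c("scenario_id", "method", "scenario_class",
                          "n_reps", "n_converged", "rate", "mc_se")], out)
message("wrote ", out)
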