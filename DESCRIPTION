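Package: vqtlbench
Title: Simulation-Based Benchmarking of Variance QTL Detection Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting variance quantitative trait loci (vQTLs)
    and for benchmarking vQTL detection methods by Monte-Carlo simulation.
    Implements ten variance-heterogeneity tests (Levene, Brown-Forsythe,
    Bartlett, Fligner-Killeen, SVLM, CLS, DRM, Z-score regression, QUAIL
    and the double generalized linear model), a gene-by-environment
    phenotype simulator with min-max-normalized additive, environmental,
    interaction and error components, covariate-adjustment and rank
    inverse-normal preprocessing variants, a false-positive-rate and power
    evaluation engine over scenario grids, and a phenotype-by-genotype
    matrix scan with permutation-based false discovery rates and an
    epistasis interaction check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quantreg,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    vcfR,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
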