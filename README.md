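# vqtlbench

Detection and simulation-based benchmarking of **variance quantitative
trait loci (vQTLs)** — genetic variants associated with differences in
phenotypic *variance* (not just the mean) across genotype groups. Variance
heterogeneity at a locus is a classic footprint of gene-by-environment
(GxE) interaction: if an allele amplifies the effect of an exposure, the
carriers of that allele are more spread out even when their mean is
unchanged.

The package is aimed at statistical geneticists who want to (i) run
variance-heterogeneity tests on their own phenotype/genotype data and
(ii) understand, by Monte-Carlo simulation, which test to trust under a
given sample size, allele frequency, exposure type and error
distribution.

## What is implemented

**Ten vQTL tests**, each mapping a trait vector `y` and an additive 0/1/2
genotype `g` to a statistic and p-value:

| method | idea |
|---|---|
| `levene`, `bf` | one-way ANOVA of distances \|y − center_g\| (center = group mean / median) |
| `bartlett` | modified LRT of equal group variances |
| `fk` | chi-squared test on normal scores of ranked median-centered distances |
| `svlm` | regress squared residuals of `y ~ g` on `g` |
| `cls` | Spearman correlation of squared residuals with `g` |
| `drm` | regress \|y − median_g\| on `g` |
| `zscore` | regress squared rank-inverse-normal scores on `g` |
| `quail` | integrated quantile-regression effect β = ∫₀^0.5 (β₁₋τ − βτ) dτ with rank-score inference |
| `dglm` | double GLM: joint mean model and log-linear dispersion model, Wald test on the genotype dispersion coefficient |

**A GxE cohort simulator.** Traits follow

```
y = a_mean·G + a_E·E + a_var·(G×E) + a_error·error ,   a_mean + a_E + a_var + a_error = 1,
```

where each component (interacting-allele dosage `G`, encoded exposure
`E`, their product, and the error draw) is min–max normalized to [0, 1]
before weighting. Exposures are binary (with exact 10/90, 30/70 or 50/50
splits), uniform(20, 70) or normal(25, 3); errors are normal,
chi-squared(df = 1) or gamma(2, 0.5); genotypes follow Hardy–Weinberg
proportions with at least 10 samples per genotype class. For binary
exposures the *variance-only coding* fixes the unexposed category at −1
and sets the exposed code to (1 − f_E)/f_E (9 for a 10% exposed
fraction), which zeroes the exposure mean so a pure interaction changes
group variances without shifting group means.

**Preprocessing variants** (exposure regressed out or not, genotype
additionally adjusted for SVLM/CLS, optional rank inverse-normal
transform), **a Monte-Carlo engine** (`run_grid`) producing
false-positive-rate and power tables over scenario × method grids with
reproducible per-cell seeds, and **a matrix scan** (`vqtl_scan`) with
permutation-based FDR and an epistasis interaction check
(`y ~ g1 + g2 + g1:g2`).

## Worked example

```r
library(vqtlbench)

# a variance-only vQTL: no mean effect, interaction weight 0.1
sc <- simulation_scenario(n = 10000, maf = 0.05, a_var = 0.1, seed = 42)
cohort <- simulate_trait(sc)
run_methods(cohort$y, cohort$g, covariates = cohort$e_raw,
            methods = c("bf", "svlm", "drm", "levene", "dglm"))
#>   method statistic  p_value effect_size   df converged
#> 1     bf     16.29 8.67e-08          NA    2      TRUE
#> 2   svlm      6.01 1.95e-09    0.000205 9998      TRUE
#> 3    drm      5.25 1.55e-07    0.002822 9998      TRUE
#> 4 levene     17.05 4.04e-08          NA    2      TRUE
#> 5   dglm      5.15 2.61e-07    0.236395    1      TRUE
```

All five tests detect the planted variance signal (p ≪ 0.05). The effect
sizes live on method-specific scales: the SVLM slope is the allele effect
on the squared residual, the DRM slope on the median-centered deviation,
and the DGLM coefficient on the log phenotypic variance.

Rejection rates over a scenario grid (here: the size of Levene's and the
Brown–Forsythe tests under a fully null model):

```r
null_sc <- simulation_scenario(n = 1000, maf = 0.05, seed = 42)
run_grid(list(null = null_sc), methods = c("levene", "bf"),
         n_reps = 200, seed = 7)[, c("method", "rate", "mc_se")]
#>   method  rate mc_se
#> 1 levene 0.065 0.017
#> 2     bf 0.070 0.018
```

Both sit within Monte-Carlo noise of the nominal 0.05. A command-line
front end for grid runs is provided as
`Rscript scripts/vqtlbench.R grid --config grid.yaml --out results.tsv --seed 1`.

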