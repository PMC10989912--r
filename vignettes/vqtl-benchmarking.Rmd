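---
title: "Benchmarking variance-QTL detection methods by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking variance-QTL detection methods by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(vqtlbench)
```

## The problem

A variance QTL (vQTL) is a genetic variant whose genotype groups differ
in phenotypic *variance*. The canonical generating mechanism is
gene-by-environment (GxE) interaction: when an allele modulates the
effect of an exposure, the trait spread grows with the dosage of that
allele even if group means stay put. Many tests have been proposed to
find such loci — classical variance-homogeneity tests (Levene,
Brown–Forsythe, Bartlett, Fligner–Killeen), regression re-phrasings
(SVLM, CLS, DRM, the Z-score method), quantile-based summaries (QUAIL)
and joint mean–dispersion models (DGLM) — and their operating
characteristics differ sharply with sample size, minor allele frequency
(MAF), exposure type and error skewness. This package implements the ten
tests and a simulation engine that measures their false positive rate
(FPR) and power under controlled GxE scenarios.

## The generative model

`simulate_trait()` draws a cohort from

$$y \;=\; a_\mathrm{mean}\,G \;+\; a_E\,E \;+\; a_\mathrm{var}\,(G\times E)
\;+\; a_\mathrm{error}\,\varepsilon,$$

with the four weights constrained to sum to one ($a_E$ is derived) and
each component min–max normalized to $[0,1]$ *before* weighting, so that
a weight is interpretable as the share of the trait range contributed by
its component. The components are:

* **$G$** — the dosage of the *interacting allele* at a single biallelic
  locus. Genotypes are stored as minor-allele counts $g \in \{0,1,2\}$
  under Hardy–Weinberg proportions, but by default the dosage entering
  the model is $2-g$: the interacting allele is the common one, which
  places the non-interacting (zero-variance) class in the small minor
  homozygote group. `interact = "minor"` flips this. The two choices are
  *not* equivalent — $(2-g)E = 2E - gE$ is not an affine function of
  $gE$ — and the flag exists precisely because the direction matters for
  power.
* **$E$** — one exposure: binary with an exact exposed fraction
  $f_E \in \{0.1, 0.3, 0.5\}$, uniform$(20, 70)$, or normal$(25, 3)$
  (defaults chosen as plausible ranges for, say, an age-like or BMI-like
  covariate). Binary categories are assigned as exactly
  `round(f_E * n)` exposed samples in randomized order, independent of
  genotype, so the stated proportions hold in every replicate rather
  than on average.
* **$G\times E$** — the elementwise product of the *raw* dosage and the
  *raw* encoded exposure, normalized after multiplication (the product
  is treated as one term, not a product of normalized terms).
* **$\varepsilon$** — normal, chi-squared ($df = 1$ by default) or
  gamma (shape 2, rate 0.5) noise; the skewed options drive the
  robustness comparisons.

### The variance-only encoding

With a binary exposure the mean trait of a genotype group with dosage
$d$ under a pure interaction is proportional to $d \cdot (f_E x_E +
(1-f_E) x_e)$. Fixing the unexposed code at $-1$ and solving for a zero
weighted mean gives the exposed code $(1-f_E)/f_E$ — 9 for a 10% exposed
fraction, 1 for a balanced design (`binary_exposure_encoding()`). Under
this coding a pure GxE effect changes group variances while leaving all
group means equal, which is what defines the *variance-only* scenarios
used for power; without it, an interaction also shifts means and the
scenario is `mean_and_variance`. Continuous exposures are not centered
and their category proportions are not controlled, so variance-only
scenarios exist only for binary exposures.

### Genotype group sizes

Group sizes must respect a floor of `min_group = 10` samples per
genotype class — tiny classes generate spurious variance signals (the
parent-of-origin artefact) and break within-group centers. The default
policy (`sampling = "fixed"`) rounds the Hardy–Weinberg expectations,
floors each class at `min_group`, and takes the deficit from the largest
class: at $n = 1000$, MAF $0.05$ the minor homozygote expectation is 2.5
and the realized count is exactly 10. The alternative
(`sampling = "multinomial"`) draws class counts multinomially and
rejection-resamples until the floor holds, with a 1,000-attempt cap and
an explicit error quoting the expected minor-homozygote count when the
constraint is hopeless. The fixed policy is the default because the
benchmark's own low-MAF, moderate-$n$ scenarios are exactly the regime
where rejection sampling fails almost surely, and because fixing group
sizes removes a nuisance source of Monte-Carlo variance from rate
estimates.

### Numerical conventions

* `minmax()` maps a constant vector to zeros instead of erroring, so
  zero-weight components degrade gracefully.
* Degenerate test inputs (zero within-group spread, constant squared
  residuals, a trait deterministic in the regressors) return the
  conservative convention $p = 1$ with an explanatory `note`, and are
  never counted as discoveries.
* Rank-based steps use average ranks for ties throughout.
* The rank inverse-normal transform uses $\Phi^{-1}((r - 0.5)/n)$; a
  Blom offset $(r - 3/8)/(n + 1/4)$ is available for sensitivity checks.

## Preprocessing routes

Following standard QTL practice the trait is adjusted before testing:
`run_method()` regresses $y$ on an intercept plus the exposure (and, for
SVLM and CLS only, also the genotype) and passes the residuals to the
test. Setting `adjust_exposure = FALSE` reproduces the
*unobserved-exposure* variant in which the raw trait enters the tests.
The optional `apply_int` switch rank-inverse-normal transforms the
residuals before every method except the Z-score test (which transforms
internally); `int_inflation_experiment()` pairs such a run with a plain
one to demonstrate that normalization converts mean effects into
spurious variance signals when errors are skewed — the reason the
package, like the comparison it implements, recommends *against*
transforming phenotypes before vQTL detection.

## Method-specific choices

* **Brown–Forsythe center**: the group median (the common software
  convention; a trimmed mean is the other textbook option).
* **Fligner–Killeen**: the prevalent modified variant that ranks
  median-centered distances, with scores
  $\Phi^{-1}(1/2 + r/(2(N+1)))$ and the sample variance of all scores in
  the denominator — this matches `stats::fligner.test` to $10^{-10}$ on
  untied data.
* **DGLM**: alternating weighted least squares for the mean and a
  gamma/log dispersion GLM on leverage-corrected squared residuals
  $d_i = e_i^2/(1-h_i)$ with prior weights $(1-h_i)/2$. Because those
  weights already carry the $\chi^2_1$ variance factor 2, the Wald test
  of the genotype dispersion coefficient fixes the gamma dispersion at 1
  (fixing it at 2 on top of the weights would inflate standard errors by
  $\sqrt 2$ and roughly decimate the size of the test). Convergence is
  declared when the dispersion deviance moves by less than `tol = 1e-8`
  (default cap 50 iterations); non-converged fits report `p = NA` and
  the evaluation engine counts them outside the rate denominator.
* **QUAIL**: the quantile grid is $\tau_k = k/(K+1)$ with $K = 100$ by
  default. The integrated effect $\beta = \int_0^{0.5}
  (\beta_{1-\tau} - \beta_\tau)\,d\tau$ is a Riemann sum of
  quantile-regression slopes (fitted with `quantreg`); note the
  *integral*, not the mean over the half-grid, which is twice as large.
  Inference does not rely on those fits: each sample receives the
  integrated quantile rank score
  $\psi_i = \overline{(a_{1-\tau,i} - a_{\tau,i})}$ built from the
  intercept-only quantile fits of the adjusted trait (with
  $a_{\tau,i} = \tau - 1\{y_i < \hat q_\tau\}$), and $\psi$ is regressed
  on the genotype with a two-sided $t$-test. Since $\psi$ depends on the
  trait only through ranks, the test is exactly exchangeable under the
  null. A genotype-permutation fallback (default 200 permutations) is
  available via `inference = "permutation"`. For rate estimation
  `run_grid()` skips the slope fits (`estimate_beta = FALSE`), which
  changes nothing about p-values.
* All tests are two-sided and rates apply the inclusive rule
  $p \le \alpha$ with $\alpha = 0.05$ by default.

## The evaluation engine

`run_grid()` derives one seed per (master seed, scenario id, replicate)
via a small string hash, so every cell is reproducible in isolation and
results are independent of execution order or grid composition — the
contract that makes cells safe to parallelize externally. Rates come
with binomial Monte-Carlo standard errors, and scenarios are classified
`null` / `mean_only` / `variance_only` / `mean_and_variance` from
$(a_\mathrm{mean}, a_\mathrm{var})$ alone; a rate is an FPR in the first
two classes and power in the others.

The packaged test-suite and acceptance runs use reduced problem sizes
chosen to keep the full suite within a coffee break while leaving
Monte-Carlo bands tight enough to be meaningful: 500 replicates for the
$n \le 10{,}000$ rate estimates, 200 replicates at $n = 200{,}000$, and
150–200 replicates for the monotonicity and inflation properties. The
original comparison used 1,000 replicates per cell; `run_grid()` does
that too if asked.

## The scan module

`vqtl_scan()` applies chosen tests across a feature × sample phenotype
matrix and a variant × sample genotype matrix (TSV or VCF input),
filtering variants to MAF $\ge 0.05$ and `min_group` $\ge 10$ and
logging skipped variants with reasons. `permutation_fdr()` estimates the
FDR at each observed p-value by permuting phenotype sample labels
against the whole genotype matrix — permuting the phenotype (rather than
single variants) preserves linkage among variants — with 20 permutations
by default and a step-up pass that makes the estimate monotone
non-decreasing in $p$. Permutations are per-feature; a genome-wide null
pool would borrow strength across features but mixes feature-specific
distributions, so it is not the default. `epistasis_interaction_test()`
checks whether a detected vQTL is explained by a two-locus interaction
via the product term of `y ~ g1 + g2 + g1:g2`.

## What the simulations do and do not show

The generator emulates a single biallelic locus with an exact
Hardy–Weinberg genotype layout, one exposure, independent samples and
i.i.d. errors. Real data add linkage disequilibrium (a mean-controlling
QTL in LD with the tested variant can masquerade as a vQTL), relatedness
and family structure, imputation uncertainty, multiple correlated
exposures, and measurement artefacts — none of which the passing tests
speak to. Scenario classes are also idealized: weights are exact
population quantities, whereas real effect sizes are estimated. The
managed-access expression datasets used for real-data replication of
vQTL findings are deliberately out of scope; the scan module is
validated on planted synthetic signals instead.

Two further limitations are worth naming. First, the min–max scaling
couples a component's weight to its realized extremes, so heavy-tailed
error draws compress the error term's effective variance in a
sample-size-dependent way; this is a property of the design being
reproduced, not a bug, but it means weights are not directly comparable
across error distributions. Second, with a normal continuous exposure at
very large $n$ the Brown–Forsythe test is measurably less powerful than
SVLM/DRM in this implementation (the exposure-adjusted excess variance
concentrates in the small minor-homozygote class, where a 2-df distance
ANOVA is inefficient relative to the 1-df dosage-trend tests), so power
claims for BF in that regime should be read with care.
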