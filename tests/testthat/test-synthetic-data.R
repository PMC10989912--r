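# Generator for gene-by-environment cohorts: genotypes, exposures,
# min-max scaling and trait assembly.

test_that("variance-only binary encoding zeroes the expected exposure mean", {
  expect_equal(unname(binary_exposure_encoding(0.1)), c(9, -1))
  expect_equal(unname(binary_exposure_encoding(0.5)), c(1, -1))
  enc <- binary_exposure_encoding(0.3)
  expect_equal(unname(enc), c(7 / 3, -1))
  # the defining property: f_E * x_exposed + (1 - f_E) * x_unexposed = 0
  for (f in c(0.05, 0.1, 0.25, 0.3, 0.5, 0.77)) {
    e <- binary_exposure_encoding(f)
    expect_equal(f * e[["x_exposed"]] + (1 - f) * e[["x_unexposed"]], 0,
                 tolerance = 1e-12)
  }
  expect_error(binary_exposure_encoding(0), "f_E")
  expect_error(binary_exposure_encoding(1), "f_E")
})

test_that("minmax rescales to [0,1], maps constants to zero and is affine-invariant", {
  expect_equal(minmax(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax(c(3, 3, 3)), c(0, 0, 0))
  # extreme interaction products under the (9, -1) coding
  expect_equal(minmax(c(-2, 18)), c(0, 1))
  expect_error(minmax(numeric(0)), "non-empty")
  set.seed(42)
  for (i in 1:5) {
    v <- rnorm(20)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(minmax(a * v + b), minmax(v), tolerance = 1e-12)
  }
})

test_that("genotype simulation honours HWE proportions and the group-size floor", {
  g <- simulate_genotypes(1000, maf = 0.05, seed = 1)
  counts <- tabulate(g + 1L, 3L)
  expect_length(g, 1000)
  expect_gte(counts[3], 10)  # HWE expectation is 2.5, floored at min_group
  expect_equal(sum(counts), 1000)

  # balanced locus: proportions near (0.25, 0.5, 0.25)
  n <- 4 * 10 * 10
  g <- simulate_genotypes(n, maf = 0.5, seed = 2)
  p_hat <- tabulate(g + 1L, 3L) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(p_hat - c(0.25, 0.5, 0.25)) < 5 * se))

  expect_error(simulate_genotypes(1000, maf = 0), "minor allele")
  expect_error(simulate_genotypes(25, maf = 0.5), "min_group")

  # determinism
  expect_identical(simulate_genotypes(500, 0.2, seed = 9),
                   simulate_genotypes(500, 0.2, seed = 9))
})

test_that("multinomial genotype sampling rejects until feasible or errors with the expectation", {
  g <- simulate_genotypes(600, maf = 0.3, seed = 3, sampling = "multinomial")
  expect_true(all(tabulate(g + 1L, 3L) >= 10))
  # expected minor-homozygote count 2.5 << 10: the cap must trip and the
  # error must report the expectation
  expect_error(
    simulate_genotypes(1000, maf = 0.05, seed = 4, sampling = "multinomial",
                       max_attempts = 50),
    "2\\.5")
})

test_that("binary exposure assignment hits the category counts exactly", {
  e <- simulate_exposure(exposure_spec("binary", f_E = 0.1), 1000, seed = 1)
  expect_equal(sum(e == 9), 100)
  expect_equal(sum(e == -1), 900)
  e01 <- simulate_exposure(
    exposure_spec("binary", f_E = 0.25, encode_variance_only = FALSE),
    200, seed = 1)
  expect_equal(sum(e01 == 1), 50)
  expect_equal(sum(e01 == 0), 150)
})

test_that("continuous exposures follow the stated distributions", {
  e <- simulate_exposure(exposure_spec("uniform"), 10000, seed = 1)
  expect_gte(min(e), 20)
  expect_lte(max(e), 70)
  expect_equal(mean(e), 45, tolerance = 0.02)
  e <- simulate_exposure(exposure_spec("normal"), 10000, seed = 1)
  expect_equal(mean(e), 25, tolerance = 0.01)
  expect_equal(sd(e), 3, tolerance = 0.05)
})

test_that("genetically associated exposure adds a_mean * G on the raw scale", {
  g <- rep(0:2, each = 10)
  spec <- exposure_spec("normal")
  base <- simulate_exposure(spec, 30, seed = 5)
  e1 <- simulate_exposure(spec, 30, g = g, a_mean = 0.3,
                          genetic_exposure = TRUE, seed = 5)
  expect_equal(e1, base + 0.3 * g)
  # zero additive weight leaves the exposure untouched
  e0 <- simulate_exposure(spec, 30, g = g, a_mean = 0,
                          genetic_exposure = TRUE, seed = 5)
  expect_identical(e0, base)
})

test_that("scenario weights must stay on the unit simplex", {
  sc <- simulation_scenario(n = 100, maf = 0.3, a_mean = 0.1, a_var = 0.2)
  expect_equal(sc$a_mean + sc$a_E + sc$a_var + sc$a_error, 1)
  expect_error(simulation_scenario(n = 100, maf = 0.3, a_mean = 0.5,
                                   a_var = 0.4, a_error = 0.2),
               "exceed")
  expect_error(simulation_scenario(n = 20, maf = 0.3), "three genotype groups")
})

test_that("simulated traits are the stated weighted sum of unit-scaled terms", {
  sc <- simulation_scenario(n = 400, maf = 0.2, a_mean = 0.1, a_var = 0.2,
                            seed = 11)
  co <- simulate_trait(sc)
  for (term in co$terms) {
    expect_equal(min(term), 0)
    expect_equal(max(term), 1)
  }
  y_hand <- 0.1 * co$terms$G + sc$a_E * co$terms$E +
    0.2 * co$terms$GxE + 0.2 * co$terms$error
  expect_equal(co$y, y_hand, tolerance = 1e-12)
  # bitwise reproducibility
  expect_identical(simulate_trait(sc)$y, co$y)
})

test_that("variance-only encoding equalizes genotype-group means of the interaction term", {
  # under the (9, -1) coding at f_E = 0.1 the six possible products
  # {0, 9, -1, 18, -2} normalize to values whose expected group means are
  # all (0 + 2) / 20 = 0.1
  sc <- simulation_scenario(n = 1e5, maf = 0.2, a_var = 0.2, seed = 13)
  co <- simulate_trait(sc)
  for (lev in 0:2) {
    m <- mean(co$terms$GxE[co$g == lev])
    n_g <- sum(co$g == lev)
    # group sd of the normalized products is at most 0.3
    expect_lt(abs(m - 0.1), 3 * 0.3 / sqrt(n_g))
  }
  # and the trait itself shows vanishing group-mean differences
  means <- tapply(co$y, co$g, mean)
  expect_lt(max(means) - min(means), 0.01)
})

test_that("a trait with no genetic terms is uncorrelated with genotype", {
  r2 <- replicate(20, {
    sc <- simulation_scenario(n = 500, maf = 0.3,
                              seed = sample.int(1e6, 1))
    co <- simulate_trait(sc)
    cor(co$y, co$g)^2
  })
  # squared correlation null quantile: qbeta(.999, 1/2, (n-2)/2)
  expect_lt(mean(r2 > qbeta(0.999, 0.5, 249)), 0.2)
})

test_that("cohort export writes the documented TSV layout", {
  sc <- simulation_scenario(n = 60, maf = 0.3, seed = 2)
  co <- simulate_trait(sc)
  path <- tempfile(fileext = ".tsv")
  write_cohort_tsv(co, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("sample_id", "y", "g", "e_raw"))
  expect_equal(tab$y, co$y, tolerance = 1e-10)
  unlink(path)
})

test_that("scenario grids expand axes and drop infeasible weight combinations", {
  grid <- scenario_grid(list(n = c(500, 1000), maf = 0.05,
                             a_mean = c(0, 0.4), a_var = c(0, 0.4)))
  # (0.4, 0.4) + a_error 0.2 = 1 is feasible; all 2*4 weight combos kept
  expect_length(grid, 8)
  expect_true(all(vapply(grid, inherits, logical(1), "simulation_scenario")))
  expect_error(scenario_grid(list(nonsense = 1)), "unknown configuration")
})
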