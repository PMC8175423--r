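# Independent oracle: the eigenvalue variance of a correlation matrix equals
# the mean squared off-diagonal correlation times (p - 1), because
# trace(R^2) = sum(lambda^2) = p + sum_{i != j} r_ij^2.
pi_oracle <- function(x) {
  r <- cor(x)
  p <- ncol(r)
  sum(r[upper.tri(r)]^2) * 2 / p
}

test_that("closed forms: independence, p = 2, duplicated columns", {
  set.seed(51)
  # exactly independent columns via an identity correlation matrix
  x <- matrix(rnorm(40), 10, 4)
  x_ind <- x %*% solve(chol(cov(x)))    # whitened: correlation exactly identity
  expect_equal(integration_index(x_ind)$raw, 0, tolerance = 1e-12)
  # p = 2 gives raw = r^2
  a <- rnorm(30); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(30)
  ii <- integration_index(cbind(a, b))
  expect_equal(ii$raw, cor(a, b)^2, tolerance = 1e-12)
  # duplicated column x3: all eigenvalues in one -> raw = p - 1
  z <- rnorm(20)
  ii3 <- integration_index(cbind(z, z, z))
  expect_equal(ii3$raw, 2, tolerance = 1e-12)
  expect_equal(sort(ii3$eigenvalues), c(0, 0, 3), tolerance = 1e-9)
})

test_that("eigenvalue route, oracle and fast identity agree on random cases", {
  set.seed(52)
  for (i in 1:25) {
    x <- matrix(rnorm(12 * 5), 12, 5)
    ii <- integration_index(x)
    expect_equal(ii$raw, pi_oracle(x), tolerance = 1e-9)
    expect_equal(ii$raw, voctrait:::.pi_raw_fast(x), tolerance = 1e-12)
    expect_equal(sum(ii$eigenvalues), 5, tolerance = 1e-9)  # trace conservation
  }
})

test_that("constant columns are removed with a warning; tiny subsets refuse", {
  set.seed(53)
  x <- cbind(rnorm(10), rnorm(10), rep(2, 10))
  expect_warning(ii <- integration_index(x), "constant")
  expect_equal(ii$p, 2)
  expect_warning(res <- integration_index(cbind(rnorm(10), rep(1, 10))))
  expect_null(res$raw)
  expect_match(res$reason, "fewer than 2")
  expect_error(integration_index(matrix(rnorm(4), 2, 2)), ">= 3 samples")
})

test_that("correction and relative scaling follow the printed formula", {
  out <- corrected_relative_pi(2, p = 3, n = 10)
  expect_equal(out$corrected, 1.8)
  expect_equal(out$relative_pct, 90)
  # raw at the random expectation centers to zero
  out0 <- corrected_relative_pi((5 - 1) / 12, p = 5, n = 12)
  expect_equal(out0$corrected, 0)
  expect_equal(out0$relative_pct, 0)
  # perfect integration tends to 100% as n grows
  expect_equal(corrected_relative_pi(9, p = 10, n = 1e9)$relative_pct, 100,
               tolerance = 1e-6)
})

test_that("permutation null: observed below q95 is not significant", {
  set.seed(54)
  x <- matrix(rnorm(12 * 6), 12, 6)
  nl <- pi_null(x, n_null = 400, seed = 7)
  expect_length(nl$null, 400)
  expect_identical(nl$significant, nl$observed_relative > nl$q95)
  expect_gt(nl$p_value, 0); expect_lte(nl$p_value, 1)
  expect_warning(pi_null(x, n_null = 50, seed = 1), "unstable")
})

test_that("subset null draws compound sets from the pool", {
  set.seed(55)
  pool <- matrix(rnorm(15 * 20), 15, 20)
  x <- pool[, 1:5]
  nl <- pi_null(x, n_null = 200, mode = "subset", pool = pool, seed = 3)
  expect_length(nl$null, 200)
  expect_error(pi_null(x, n_null = 100, mode = "subset", seed = 3),
               "requires a compound pool")
})

test_that("a strongly integrated block is flagged against its null", {
  set.seed(56)
  x <- one_factor_block(30, 6, 0.8)
  nl <- pi_null(x, n_null = 500, seed = 11)
  expect_true(nl$significant)
  expect_lt(nl$p_value, 0.05)
})

test_that("relative integration rises monotonically with the planted loading", {
  meds <- vapply(c(0, 0.3, 0.6, 0.9), function(lam) {
    vals <- vapply(1:8, function(i) {
      set.seed(1000 + i)
      x <- one_factor_block(30, 6, lam)
      corrected_relative_pi(integration_index(x)$raw, 6, 30)$relative_pct
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("the panel localises planted covariation and reports boundaries", {
  runs <- lapply(1:5, function(s) {
    sim <- simulate_volatilome(simulation_scenario(
      n_species = 32, n_ptr_compounds = 44, n_gc_compounds = 22, sparsity = 0,
      biomarker_spec = data.frame(label = character(0), class_value = character(0),
                                  compound_id = character(0), delta = numeric(0)),
      covariation_spec = data.frame(trophic_mode = "saprotrophic",
                                    structural_class = "carboxylic_acid",
                                    loading = 0.9),
      seed = 50 + s))
    merged <- merge_platforms(sim$ptr, sim$gc)
    suppressWarnings(pi_panel(merged, sim$annotation, sim$truth$classes,
                              n_null = 300, seed = s))
  })
  panel <- runs[[1]]
  expect_true(all(c("trophic_mode", "structural_class", "relative_pct",
                    "p_value", "significant", "reason") %in% names(panel)))
  # every computed row satisfies the theoretical raw-index range
  comp <- panel[!is.na(panel$raw), ]
  expect_true(all(comp$raw >= 0 & comp$raw <= comp$p_compounds - 1))

  planted_sig <- vapply(runs, function(p)
    isTRUE(p$significant[p$trophic_mode == "saprotrophic" &
                         p$structural_class == "carboxylic_acid"]), logical(1))
  other_sig <- vapply(runs, function(p)
    sum(p$significant[p$trophic_mode %in% c("mycorrhizal", "phytopathogenic",
                                            "mycoparasitic") &
                      p$structural_class == "carboxylic_acid"], na.rm = TRUE),
    numeric(1))
  # the planted cell lights up in most runs; its class stays mostly quiet
  # in the other guilds
  expect_gte(sum(planted_sig), 4)
  expect_lte(median(other_sig), 1)
})
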