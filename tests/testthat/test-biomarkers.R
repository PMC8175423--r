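test_that("stratified split keeps proportions and is seed-deterministic", {
  y <- factor(rep(letters[1:4], each = 12))
  sp <- stratified_split(y, 0.25, seed = 5)
  expect_equal(length(sp$test), 12)
  expect_true(all(table(y[sp$test]) == 3))
  expect_true(all(table(y[sp$train]) == 9))
  sp2 <- stratified_split(y, 0.25, seed = 5)
  expect_identical(sp, sp2)
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.25, seed = 1),
               "singleton class.*a")
})

test_that("upsampling balances to the majority class with exact row copies", {
  set.seed(61)
  x <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- factor(rep(c("big", "small"), c(9, 3)))
  bal <- upsample_minority(x, y, seed = 2)
  expect_true(all(table(bal$labels) == 9))
  added <- bal$x[-(1:12), , drop = FALSE]
  for (i in seq_len(nrow(added)))
    expect_true(any(apply(x[10:12, , drop = FALSE], 1, identical, added[i, ])))
  # already balanced input is untouched
  y2 <- factor(rep(c("a", "b"), each = 6))
  bal2 <- upsample_minority(x, y2, seed = 2)
  expect_identical(dim(bal2$x), dim(x))
})

test_that("RFE recovers planted informative features", {
  set.seed(62)
  n <- 120; p <- 50
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 1:5] <- x[y == "b", 1:5] + 3
  res <- rfe_wrapper(x, y, "random_forest", subset_grid = c(5, 10, 25, 50),
                     cv_folds = 5, seed = 7, ntree = 150)
  expect_true(all(sprintf("f%02d", 1:5) %in% res$ranking[1:8]))
  expect_lte(res$optimal_size, 10)
  expect_identical(res$top15, head(res$ranking, 15))
  expect_warning(rfe_wrapper(x[, 1:8], y, "random_forest",
                             subset_grid = c(5, 20), cv_folds = 3,
                             seed = 1, ntree = 50), "clamped")
})

test_that("RFE on permuted labels stays near chance at every subset size", {
  set.seed(63)
  n <- 60; p <- 20
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- factor(sample(rep(c("a", "b"), each = n / 2)))
  res <- rfe_wrapper(x, y, "bagged_trees", subset_grid = c(5, 10, 20),
                     cv_folds = 5, seed = 2, ntree = 100)
  expect_true(all(abs(res$cv_accuracy - 0.5) < 0.25))
})

test_that("embedded RF ranks planted features highly and is deterministic", {
  set.seed(64)
  n <- 90; p <- 40
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  x[y == "b", 1:3] <- x[y == "b", 1:3] + 3
  x[y == "c", 4:5] <- x[y == "c", 4:5] + 3
  r1 <- embedded_rf(x, y, cv_folds = 5, seed = 9, ntree = 150)
  expect_gte(sum(sprintf("f%02d", 1:5) %in% r1$ranking[1:5]), 4)
  r2 <- embedded_rf(x, y, cv_folds = 5, seed = 9, ntree = 150)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$best_mtry, r2$best_mtry)
})

test_that("duplicate feature columns still yield a total ranking order", {
  set.seed(65)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("u1", "u2", "d1", "d2")))
  x[, "d2"] <- x[, "d1"]
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", c("d1", "d2")] <- x[y == "b", c("d1", "d2")] + 2
  r <- embedded_rf(x, y, cv_folds = 4, seed = 3, ntree = 100)
  expect_identical(sort(r$ranking), sort(colnames(x)))
  expect_equal(anyDuplicated(r$ranking), 0)
})

test_that("final-model metrics follow exact binomial arithmetic", {
  set.seed(66)
  # perfectly separable: accuracy 1, p = NIR^n_test
  n <- 48
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 1] <- x[y == "b", 1] + 20
  sp <- stratified_split(y, 0.25, seed = 4)
  fin <- finalize_model(x[sp$train, ], y[sp$train], x[sp$test, ], y[sp$test],
                        predictors = colnames(x), seed = 8)
  expect_equal(fin$accuracy, 1)
  expect_equal(fin$nir, 0.5)
  expect_equal(fin$p_value, 0.5^12, tolerance = 1e-12)
  expect_equal(unname(fin$sensitivity), c(1, 1))
  expect_error(finalize_model(x[sp$train, ], y[sp$train], x[sp$test, ],
                              y[sp$test], predictors = "nope", seed = 1),
               "absent")
})

test_that("a class with no test samples reports null sensitivity", {
  set.seed(67)
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y_train <- factor(rep(c("a", "b", "c"), length.out = 30),
                    levels = c("a", "b", "c"))
  y_test <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b", "c"))
  fin <- finalize_model(x[1:30, ], y_train, x[31:40, ], y_test,
                        predictors = colnames(x), seed = 2)
  expect_true(is.na(fin$sensitivity[["c"]]))
})

test_that("consensus intersects passing models and averages ranks/metrics", {
  mk <- function(rank_order, acc, p) {
    list(ranking = rank_order, top15 = head(rank_order, 15),
         accuracy = acc, p_value = p,
         sensitivity = c(a = acc, b = acc))
  }
  feats <- sprintf("f%02d", 1:20)
  m1 <- mk(feats, 0.95, 1e-5)
  m2 <- mk(feats[c(2, 1, 16:20, 3:15)], 0.90, 1e-4)
  m3 <- mk(feats[c(2, 1, 17:20, 16, 3:15)], 0.85, 1e-3)
  cons <- consensus_biomarkers(list(rf_rfe = m1, bagged_rfe = m2, rf_embedded = m3))
  # f1 and f2 are in every top15; mean ranks: f1 (1+2+2)/3, f2 (2+1+1)/3
  expect_true(all(c("f01", "f02") %in% cons$consensus$predictor))
  expect_equal(cons$consensus$mean_rank[cons$consensus$predictor == "f02"], 4 / 3)
  expect_equal(cons$consensus$mean_rank[cons$consensus$predictor == "f01"], 5 / 3)
  expect_equal(cons$mean_accuracy, mean(c(0.95, 0.90, 0.85)), tolerance = 1e-12)
  expect_equal(cons$mean_p_value, mean(c(1e-5, 1e-4, 1e-3)), tolerance = 1e-12)
  # a model under the accuracy bar is excluded and noted
  m3_bad <- mk(feats, 0.74, 1e-3)
  cons2 <- consensus_biomarkers(list(rf_rfe = m1, bagged_rfe = m2,
                                     rf_embedded = m3_bad))
  expect_identical(cons2$passing_models, c("rf_rfe", "bagged_rfe"))
  expect_equal(cons2$mean_accuracy, mean(c(0.95, 0.90)), tolerance = 1e-12)
  expect_match(cons2$note, "2 of 3")
  # insignificant model excluded; none passing -> empty consensus with reason
  cons3 <- consensus_biomarkers(list(a = mk(feats, 0.95, 0.2),
                                     b = mk(feats, 0.7, 1e-5)))
  expect_equal(nrow(cons3$consensus), 0)
  expect_match(cons3$note, "no model")
})

test_that("the task runner never lets test samples into selection", {
  sim <- simulate_volatilome(simulation_scenario(
    n_species = 16, n_ptr_compounds = 40, n_gc_compounds = 10, seed = 68))
  rep <- run_biomarker_task(sim$ptr, sim$annotation, "trophic_mode", seed = 1,
                            cv_folds = 5, ntree = 100,
                            subset_grid = c(5, 10, 20, 40))
  expect_s3_class(rep, "biomarker_report")
  expect_equal(rep$n_train + rep$n_test, nrow(sim$ptr))
  # the split is reconstructable and disjoint
  expect_equal(rep$n_test, 12)
  for (m in rep$models) {
    expect_lte(length(m$top15), 15)
    expect_true(m$accuracy >= 0 && m$accuracy <= 1)
  }
})
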