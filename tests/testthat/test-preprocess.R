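test_that("reagent-ion normalisation follows the 1e6 scaling elementwise", {
  expect_equal(normalize_reagent_ions(500, 2e6), 250)
  expect_equal(normalize_reagent_ions(0, 5e5), 0)
  expect_equal(normalize_reagent_ions(c(1, 2, 4), 2e6), c(0.5, 1, 2))
  expect_error(normalize_reagent_ions(10, 0), "positive")
  expect_error(normalize_reagent_ions(10, -3), "positive")
})

test_that("background subtraction interpolates, clips, and guards inputs", {
  # constant background
  expect_equal(subtract_background(1.5, 12, 0:4, rep(5, 5)), 7)
  # sample below the background clips to zero
  expect_equal(subtract_background(2, 1, 0:4, rep(5, 5)), 0)
  # the natural spline through collinear points is the line: bg(1.5) = 1.5
  expect_equal(subtract_background(1.5, 2.5, 0:3, 0:3), 1.0, tolerance = 1e-9)
  # duplicate background timestamps are averaged first
  expect_equal(subtract_background(1.5, 12, c(0, 0, 1, 2, 3), c(4, 6, 5, 5, 5)),
               7, tolerance = 1e-9)
  expect_error(subtract_background(0.5, 3, c(0, 1, 2), c(1, 1, 1)),
               "linear")
  expect_equal(subtract_background(0.5, 3, c(0, 1, 2), c(1, 1, 1),
                                   method = "linear"), 2)
  expect_error(subtract_background(9, 3, 0:4, rep(1, 5)), "span")
})

test_that("area/time normalisation is homogeneous with platform defaults", {
  expect_equal(area_time_normalize(140, 2, 70), 1)
  expect_equal(area_time_normalize(140, 4, 70), 0.5)
  expect_equal(default_accumulation_minutes("PTR"), 70)
  expect_equal(default_accumulation_minutes("GC"), 960)
  expect_error(area_time_normalize(1, 0, 70), "positive")
})

test_that("ncps to pmol conversion flags unconvertible compounds", {
  v <- c(a = 20, b = 8)
  out <- ncps_to_pmol(v, c(a = 10), conversion_constant = 1)
  expect_equal(unname(out$values["a"]), 2)
  expect_equal(unname(out$values["b"]), 8)      # unchanged
  expect_identical(out$unconverted, "b")
  # strictly monotone in ncps
  expect_true(all(diff(ncps_to_pmol(setNames(1:5, letters[1:5]),
                                    setNames(rep(2, 5), letters[1:5]))$values) > 0))
  expect_error(ncps_to_pmol(v, c(a = -1)), "positive")
})

test_that("isotopologue flagging uses the 13C spacing and abundance window", {
  cmp <- data.frame(compound_id = c("PTR_001", "PTR_002", "PTR_003"),
                    platform = "PTR", mz = c(59.049, 60.0524, 90.000),
                    retention_index = NA_real_, annotation = "",
                    structural_class = "ketone", cluster_letter = NA,
                    is_isotopologue = FALSE, fragment_group = NA,
                    stringsAsFactors = FALSE)
  v <- matrix(rep(c(100, 3.3, 50), each = 4), 4, 3)
  colnames(v) <- cmp$compound_id
  m <- toy_matrix(v)
  out <- flag_isotopologues(cmp, m)
  # 60.0524 - 59.049 = 1.0034 ~ 13C; ratio 0.033 = 3 carbons x 1.1%
  expect_identical(out$is_isotopologue, c(FALSE, TRUE, FALSE))
  expect_identical(colnames(drop_isotopologues(m, out)), c("PTR_001", "PTR_003"))
  # ratio 10x the expectation is left alone
  v2 <- v; v2[, 2] <- 33
  out2 <- flag_isotopologues(cmp, toy_matrix(v2))
  expect_false(any(out2$is_isotopologue))
  # no mass pair within tolerance -> no flags
  cmp3 <- cmp; cmp3$mz <- c(59.049, 75.3, 90.0)
  expect_false(any(flag_isotopologues(cmp3, m)$is_isotopologue))
})

test_that("fragment groups are connected components above the r2 threshold", {
  set.seed(6)
  x <- rnorm(50, 10, 2)
  v <- cbind(a = x, b = 3 * x, c = rnorm(50, 10), d = rnorm(50, 10),
             e = rep(1, 50))
  m <- toy_matrix(pmax(v, 0), n_rep = 1)
  colnames(m) <- colnames(v)
  fg <- group_fragments(m)
  expect_identical(fg$groups[["a"]], fg$groups[["b"]])
  expect_false(is.na(fg$groups[["a"]]))
  expect_true(is.na(fg$groups[["c"]]))      # independent noise stays single
  expect_true(is.na(fg$groups[["d"]]))
  expect_true(is.na(fg$groups[["e"]]))      # constant column: no edges
  collapsed <- group_fragments(m, collapse = TRUE)$matrix
  expect_equal(ncol(collapsed), 4)
  expect_equal(unname(unclass(collapsed)[, "frag_a"]),
               unname(unclass(m)[, "a"] + unclass(m)[, "b"]))
})

test_that("component semantics are transitive through shared members", {
  # r2(A,B) and r2(B,C) high, r2(A,C) moderate -> one group of three
  set.seed(9)
  f1 <- rnorm(200); f2 <- rnorm(200)
  a <- f1; b <- 0.8 * f1 + 0.6 * f2; c_ <- f2
  v <- cbind(A = a, B = b, C = c_) + 10
  m <- toy_matrix(pmax(v, 0)); colnames(m) <- c("A", "B", "C")
  r2 <- cor(unclass(m))^2
  expect_gt(r2["A", "B"], 0.3); expect_gt(r2["B", "C"], 0.3)
  expect_lt(r2["A", "C"], 0.3)
  fg <- group_fragments(m, r2_threshold = 0.3)
  expect_identical(fg$groups[["A"]], fg$groups[["B"]])
  expect_identical(fg$groups[["B"]], fg$groups[["C"]])
})

test_that("retention indices interpolate linearly over the alkane series", {
  alk <- setNames(seq(5, 37, by = 2), 9:25)
  expect_equal(kovats_ri(alk[["12"]], alk), 1200)
  expect_equal(kovats_ri(11, setNames(c(10, 12), c(10, 11))), 1050)
  expect_error(kovats_ri(3, alk), "outside the alkane span")
  expect_error(kovats_ri(40, alk), "outside the alkane span")
  expect_error(kovats_ri(10, setNames(c(5, 5), c(10, 11))), "strictly increasing")
  # strictly increasing in rt, and inverse recovers rt to 1e-9
  rts <- seq(5.1, 36.9, length.out = 41)
  ri <- kovats_ri(rts, alk)
  expect_true(all(diff(ri) > 0))
  expect_equal(kovats_rt(ri, alk), rts, tolerance = 1e-9)
})

test_that("internal-standard normalisation rescales and is idempotent", {
  expect_equal(internal_standard_normalize(c(1, 2), 5, 5), c(1, 2))
  expect_equal(internal_standard_normalize(c(1, 2), 2.5, 5), c(2, 4))
  once <- internal_standard_normalize(c(3, 7), 2, 6)
  expect_equal(internal_standard_normalize(once, 6, 6), once)
  expect_error(internal_standard_normalize(1, 0, 5), "positive")
})

test_that("the PTR chain preserves nonnegativity end to end", {
  set.seed(2)
  cps <- runif(20, 0, 50)
  ncps <- normalize_reagent_ions(cps, 1.7e6)
  corr <- subtract_background(rep(2, 20), ncps, 0:4, rep(mean(ncps), 5))
  final <- area_time_normalize(corr, 3.2, 70)
  expect_true(all(final >= 0))
})
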