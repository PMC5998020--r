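test_that("the threshold grid is 20..250 nm in 10 nm steps", {
  tg <- threshold_grid()
  expect_length(tg, 24)
  expect_equal(tg[1], 20)
  expect_equal(tg[24], 250)
  expect_equal(unique(diff(tg)), 10)
})

test_that("ROI feature vectors have the full 32 x 24 registry shape", {
  expect_length(measure_registry(), 32)
  set.seed(41)
  roi <- as_roi(matrix(runif(90, 0, 400), ncol = 3))
  fv <- roi_features(roi)
  expect_equal(dim(fv$values), c(32, 24))
  expect_length(as.vector(fv$values), 768)
  expect_false(fv$missing)
  expect_false(any(is.nan(fv$values)))
  # determinism
  expect_equal(roi_features(roi)$values, fv$values)
})

test_that("degree features track the triangle geometry across thresholds", {
  tri <- cbind(c(0, 50, 25), c(0, 0, 25 * sqrt(3)), 0)  # all pairs at 50 nm
  fv <- roi_features(as_roi(tri))
  deg <- fv$values["uwAvgDeg", ]
  expect_equal(unname(deg[fv$thresholds < 50]), rep(0, 3))
  expect_equal(unname(deg[fv$thresholds >= 50]), rep(2, 21))
})

test_that("degenerate ROIs yield a flagged all-missing vector", {
  fv <- roi_features(as_roi(matrix(0, 1, 3)))
  expect_true(fv$missing)
  expect_true(all(is.na(fv$values)))
})

test_that("Mann-Whitney p-values follow the exact small-sample law", {
  expect_equal(mw_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # complete separation at n = m = 3: exact two-sided p = 0.1
  expect_equal(mw_test(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(mw_test(c(10, 11, 12), c(1, 2, 3)),
               mw_test(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(mw_test(rep(5, 4), rep(5, 6)), 1)  # constant pooled sample
  expect_error(mw_test(numeric(0), 1:3), "empty")
})

test_that("L2-norm aggregation is conservative and Bonferroni-corrected", {
  m <- function(x) matrix(x, 32, 24)
  sig <- aggregate_pvalues(list(m(0.01), m(0.01), m(0.01)))
  expect_equal(sig$p_combined[1, 1], sqrt(3) * 0.01)
  expect_equal(sig$n_comparisons, 768)
  # 0.01732 < 0.05 / 768 is false -> not significant despite tiny p's
  expect_false(sig$significant_mask[1, 1])
  tiny <- aggregate_pvalues(list(m(1e-6), m(1e-6), m(1e-6)))
  expect_true(all(tiny$significant_mask))
  # any non-significant experiment dominates
  dom <- aggregate_pvalues(list(m(0.01), m(0.01), m(1)))
  expect_true(all(dom$p_combined > 1))
  expect_false(any(dom$significant_mask))
  # single experiment: combined equals its own p
  one <- aggregate_pvalues(list(m(0.3)))
  expect_equal(one$p_combined[5, 5], 0.3)
  expect_error(aggregate_pvalues(list(m(0.1), matrix(0.1, 2, 2))), "shape")
  # monotone dominance property
  set.seed(12)
  p1 <- matrix(runif(12), 3, 4); p2 <- matrix(runif(12), 3, 4)
  c1 <- aggregate_pvalues(list(p1, p2))$p_combined
  c2 <- aggregate_pvalues(list(p1 + 0.1, p2))$p_combined
  expect_true(all(c2 >= c1))
})

test_that("population p-value maps flag the planted discriminative scale", {
  # population A: clustered at ~ 150 nm scale; population B: uniform
  make_fv <- function(clustered, seed) {
    set.seed(seed)
    if (clustered) {
      centers <- matrix(runif(5 * 3, 200, 1300), ncol = 3)
      pts <- do.call(rbind, lapply(seq_len(5), function(k)
        sweep(matrix(rnorm(120, 0, 40), ncol = 3), 2, centers[k, ], "+")))
    } else {
      pts <- matrix(runif(600, 0, 1500), ncol = 3)
    }
    roi_features(as_roi(pts), modularity = FALSE)
  }
  fa <- lapply(1:4, function(s) make_fv(TRUE, s))
  fb <- lapply(1:4, function(s) make_fv(FALSE, 100 + s))
  p <- population_pvalues(fa, fb)
  expect_equal(dim(p), c(32, 24))
  # degree at the cluster scale discriminates strongly
  expect_lt(p["uwAvgDeg", "T150"], 0.05)
})

test_that("the random forest separates planted classes and not noise", {
  set.seed(55)
  X <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 3), 20))
  y <- rep(c("a", "b"), each = 20)
  fit <- rf_fit(X, y, n_trees = 60, seed = 3)
  expect_equal(rf_predict(fit, X), y)         # separable training data
  Xnew <- rbind(matrix(rnorm(100, 0), 10), matrix(rnorm(100, 3), 10))
  expect_equal(rf_predict(fit, Xnew), rep(c("a", "b"), each = 10))
  # deterministic given seed
  fit2 <- rf_fit(X, y, n_trees = 60, seed = 3)
  expect_equal(rf_predict(fit2, Xnew), rf_predict(fit, Xnew))
})
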