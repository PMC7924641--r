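test_that("fused concatenation has width 1074 + 1010 + 690 = 2774 in canonical order", {
  ids <- sprintf("s%02d", 1:4)
  mk <- function(d, backbone) {
    feature_matrix(matrix(rnorm(4 * d), 4), provenance = "stf",
                   backbone = backbone, sample_ids = ids)
  }
  sets <- list(mk(690L, "mobilenet"), mk(1074L, "resnet50"),
               mk(1010L, "densenet201"))
  fused <- concat_fused(sets)
  expect_identical(dim(fused), c(4L, 2774L))
  expect_identical(attr(fused, "provenance"), "fused")
  # canonical order: resnet50 block first despite the shuffled input order
  expect_equal(unclass(fused)[, 1:1074], unclass(sets[[2]])[, 1:1074],
               ignore_attr = TRUE)
  # single element: identity; row cardinality preserved
  expect_identical(concat_fused(sets[2]), sets[[2]])
  expect_identical(nrow(fused), 4L)
  # row-order mismatch is an error
  bad <- mk(100L, "resnet50"); rownames(bad) <- rev(ids)
  expect_error(concat_fused(list(sets[[1]], bad)), "row order")
})

test_that("row-wise DCT-II matches the naive cosine-sum oracle and is unitary", {
  set.seed(13)
  x <- matrix(rnorm(3 * 16), 3)
  y <- dct_rows(x)
  for (i in 1:3) {
    expect_lt(max(abs(y[i, ] - oracle_dct(x[i, ]))), 1e-10)
  }
  # constant row: all energy in the DC coefficient
  cst <- matrix(2.5, 1, 10)
  yc <- dct_rows(cst)
  expect_equal(yc[1, 1], 2.5 * sqrt(10), tolerance = 1e-10)
  expect_lt(max(abs(yc[1, -1])), 1e-10)
  # inverse recovers the input; Parseval holds per row
  expect_lt(max(abs(dct_rows(y, inverse = TRUE) - x)), 1e-10)
  expect_equal(rowSums(y^2), rowSums(x^2), tolerance = 1e-9)
})

test_that("DCT truncation keeps the first n coefficients", {
  set.seed(14)
  x <- feature_matrix(matrix(rnorm(5 * 64), 5), provenance = "fused")
  out <- reduce_dct(x, 10L)
  expect_identical(dim(out$scores), c(5L, 10L))
  expect_identical(out$model$retained, 10L)
  expect_equal(unclass(out$scores), dct_rows(x)[, 1:10], tolerance = 1e-12,
               ignore_attr = TRUE)
  # n = width: invertible representation
  full <- reduce_dct(x, 64L)
  expect_lt(max(abs(dct_rows(unclass(full$scores), inverse = TRUE) -
                      unclass(x))), 1e-10)
  # constant rows: n = 1 retains all energy
  cst <- feature_matrix(matrix(3, 4, 16), provenance = "fused")
  r1 <- reduce_dct(cst, 1L)
  expect_equal(rowSums(unclass(r1$scores)^2), rowSums(unclass(cst)^2),
               tolerance = 1e-9)
  expect_error(reduce_dct(x, 0L), "range")
  expect_error(reduce_dct(x, 65L), "range")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  x <- matrix(c(2.0, 0.5, -1.0, 3.0,
                1.0, -0.5, 0.25, 2.0,
                0.0, 1.5, -2.0, 1.0), nrow = 4)
  model <- fit_pca(x, 3L)
  ev_oracle <- sort(eigen(stats::cov(x), symmetric = TRUE)$values,
                    decreasing = TRUE)
  expect_equal(model$sdev^2, ev_oracle[1:3], tolerance = 1e-10)
  # components orthonormal, variances non-increasing
  R <- model$rotation
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
  expect_true(all(diff(model$sdev) <= 1e-12))
  # rank n-1 reconstruction captures the whole spectrum (n-1 nonzero modes)
  scores <- unclass(apply_reduction(model, x))
  recon <- scores %*% t(R)
  resid <- sweep(x, 2, model$center) - recon
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("PCA on collinear points returns the line direction", {
  t <- c(-2, -1, 1, 2)
  x <- cbind(t, 0, 0, 0)
  model <- fit_pca(x, 1L)
  expect_equal(abs(model$rotation[, 1]), c(1, 0, 0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_pca(x, 4L), "range")
})

test_that("fitted reductions project deterministically and never refit", {
  set.seed(15)
  xtr <- matrix(rnorm(8 * 20), 8)
  rownames(xtr) <- sprintf("t%d", 1:8)
  model <- fit_pca(xtr, 3L)
  expect_identical(model$fit_sample_ids, rownames(xtr))
  s1 <- unclass(apply_reduction(model, xtr))
  # training-time scores reproduced exactly on the fitting rows
  pr <- stats::prcomp(xtr, rank. = 3L)
  expect_equal(s1, pr$x[, 1:3], tolerance = 1e-10, ignore_attr = TRUE)
  # affine contract: shifting all rows by c moves scores by the projected c
  cshift <- rnorm(20)
  s2 <- unclass(apply_reduction(model, sweep(xtr, 2, -cshift)))
  expect_equal(s2 - s1,
               matrix(rep(cshift %*% model$rotation, each = 8), 8),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(apply_reduction(model, xtr[, 1:10]), "width")
})

test_that("the dimension search returns the smallest maximiser of the profile", {
  # stated tie-break on a synthetic score profile
  expect_identical(select_smallest_max(c(100L, 200L, 300L),
                                       c(0.90, 0.95, 0.95)), 200L)
  expect_identical(select_smallest_max(c(50L), c(0.77)), 50L)
  # grid-order invariance
  expect_identical(select_smallest_max(c(300L, 100L, 200L),
                                       c(0.95, 0.90, 0.95)), 200L)
})

test_that("sequential forward search scores candidates by leakage-free repeated CV", {
  fused <- small_fused_features()
  set <- small_fixture()
  y <- factor(set$class_names[set$labels], levels = set$class_names)
  res <- sequential_forward_search(fused, y, method = "pca",
                                   candidates = c(10L, 2L, 5L),
                                   cv = cv_config(4L, 2L, base_seed = 3L))
  expect_identical(res$grid$candidate, c(2L, 5L, 10L))
  expect_true(all(res$grid$mean_accuracy >= 0 & res$grid$mean_accuracy <= 1))
  # chosen score is the maximum, hence >= the smallest candidate's score
  chosen_score <- res$grid$mean_accuracy[res$grid$candidate == res$chosen]
  expect_gte(chosen_score, res$grid$mean_accuracy[1])
  # grid ordering does not change the outcome
  res2 <- sequential_forward_search(fused, y, method = "pca",
                                    candidates = c(5L, 10L, 2L),
                                    cv = cv_config(4L, 2L, base_seed = 3L))
  expect_identical(res$grid, res2$grid)
  expect_identical(res$chosen, res2$chosen)
  # infeasible candidates are skipped with a warning; all-infeasible errors
  expect_warning(
    res3 <- sequential_forward_search(fused, y, method = "pca",
                                      candidates = c(5L, 5000L),
                                      cv = cv_config(4L, 1L, base_seed = 3L)),
    "infeasible")
  expect_identical(res3$grid$candidate, 5L)
  expect_error(
    suppressWarnings(sequential_forward_search(
      fused, y, method = "pca", candidates = 5000L,
      cv = cv_config(4L, 1L, base_seed = 3L))), "feasible")
})
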