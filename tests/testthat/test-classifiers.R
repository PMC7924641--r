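toy_2d <- function() {
  # two linearly separable clusters with margin, 4 points per class
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
             c(4, 4), c(5, 4), c(4, 5), c(5, 5))
  list(x = x, y = factor(rep(c("a", "b"), each = 4)))
}

test_that("all five classifier kinds satisfy the fit/predict contract", {
  set.seed(21)
  x <- matrix(rnorm(40 * 12), 40)
  rownames(x) <- sprintf("r%02d", 1:40)
  y <- factor(rep(c("u", "v"), 20))
  x[y == "v", 1:3] <- x[y == "v", 1:3] + 3
  for (kind in c("lda", "svm_linear", "svm_cubic", "knn1",
                 "subspace_discriminant_ensemble")) {
    fit <- fit_classifier(classifier_spec(kind), x, y)
    expect_identical(fit$fit_sample_ids, rownames(x))
    pred <- predict(fit, x)
    expect_length(pred, 40L)
    expect_s3_class(pred, "factor")
    expect_identical(levels(pred), c("u", "v"))
    # duplicated row gets identical predictions
    two <- predict(fit, x[c(1, 1), ])
    expect_identical(two[1], two[2])
    # width mismatch is a data error
    expect_error(predict(fit, x[, 1:5]), "width")
  }
  expect_error(fit_classifier(classifier_spec("lda"), x, rep("u", 40)),
               "single class")
})

test_that("1-NN memorises its training set and breaks ties by lowest index", {
  set.seed(22)
  x <- matrix(rnorm(30 * 5), 30)
  y <- factor(rep(c("p", "q", "r"), 10))
  fit <- fit_classifier(classifier_spec("knn1"), x, y)
  expect_identical(as.character(predict(fit, x)), as.character(y))
  # agreement with class::knn where no distance ties exist
  skip_if_not_installed("class")
  xte <- matrix(rnorm(15 * 5), 15)
  ours <- predict(fit, xte)
  ref <- class::knn(x, xte, y, k = 1)
  expect_identical(as.character(ours), as.character(ref))
  # exact-tie case: two training points at the same location, different
  # labels; the lower training index must win
  xt <- rbind(c(0, 0), c(0, 0), c(9, 9))
  yt <- factor(c("a", "b", "b"))
  ftie <- fit_classifier(classifier_spec("knn1"), xt, yt)
  expect_identical(as.character(predict(ftie, rbind(c(0, 0)))), "a")
})

test_that("pseudo-inverse LDA agrees with the reference implementation when well-conditioned", {
  skip_if_not_installed("MASS")
  set.seed(23)
  x <- matrix(rnorm(60 * 4), 60)
  y <- factor(rep(c("a", "b", "c"), 20))
  x[y == "b", 1] <- x[y == "b", 1] + 2.5
  x[y == "c", 2] <- x[y == "c", 2] + 2.5
  fit <- fit_classifier(classifier_spec("lda"), x, y)
  ref <- MASS::lda(x, y)
  xte <- matrix(rnorm(25 * 4), 25)
  expect_identical(as.character(predict(fit, xte)),
                   as.character(predict(ref, xte)$class))
  # posteriors agree too
  P <- predict(fit, xte, type = "prob")
  expect_equal(unname(P), unname(predict(ref, xte)$posterior),
               tolerance = 1e-6)
  # and it stays defined with more features than samples
  xw <- matrix(rnorm(10 * 50), 10)
  yw <- factor(rep(c("a", "b"), 5))
  xw[yw == "b", ] <- xw[yw == "b", ] + 1
  fw <- fit_classifier(classifier_spec("lda"), xw, yw)
  expect_length(predict(fw, xw), 10L)
})

test_that("the degenerate subspace ensemble collapses to plain LDA", {
  set.seed(24)
  x <- matrix(rnorm(30 * 8), 30)
  y <- factor(rep(c("a", "b"), 15))
  x[y == "b", 1] <- x[y == "b", 1] + 2
  ens <- fit_classifier(classifier_spec("subspace_discriminant_ensemble",
                                        n_learners = 1L, subspace_dim = 8L),
                        x, y)
  plain <- fit_classifier(classifier_spec("lda"), x, y)
  xte <- matrix(rnorm(20 * 8), 20)
  expect_identical(predict(ens, xte), predict(plain, xte))
  expect_equal(predict(ens, xte, type = "prob"),
               predict(plain, xte, type = "prob"), tolerance = 1e-12)
})

test_that("ensemble subspace draws are seeded, recorded, and clamped", {
  set.seed(25)
  x <- matrix(rnorm(24 * 2000), 24)
  y <- factor(rep(c("a", "b"), 12))
  x[y == "b", 1:50] <- x[y == "b", 1:50] + 1.5
  spec <- classifier_spec("subspace_discriminant_ensemble", n_learners = 5L,
                          subspace_dim = 1024L, seed = 77L)
  f1 <- fit_classifier(spec, x, y)
  f2 <- fit_classifier(spec, x, y)
  expect_identical(f1$model$subsets, f2$model$subsets)
  expect_length(f1$model$subsets, 5L)
  expect_true(all(lengths(f1$model$subsets) == 1024L))
  expect_identical(predict(f1, x), predict(f2, x))
  # subspace_dim clamps to the feature count
  xs <- x[, 1:6]
  fs <- fit_classifier(spec, xs, y)
  expect_true(all(lengths(fs$model$subsets) == 6L))
})

test_that("SVMs separate a linearly separable toy problem", {
  toy <- toy_2d()
  for (kind in c("svm_linear", "svm_cubic")) {
    fit <- fit_classifier(classifier_spec(kind), toy$x, toy$y)
    expect_identical(as.character(predict(fit, toy$x)),
                     as.character(toy$y))
  }
})

test_that("every classifier beats the permutation null on fused fixture features", {
  fused <- study_fused_features()
  set <- study_fixture()
  y <- factor(set$class_names[set$labels], levels = set$class_names)
  # work on a PCA-reduced representation (as in the full cascade) to keep
  # the SVM kinds fast; stratified 80/20 split
  red <- apply_reduction(fit_pca(fused, 25L), fused)
  te <- which(seq_along(y) %% 5 == 0); tr <- setdiff(seq_along(y), te)
  for (kind in c("lda", "svm_linear", "svm_cubic", "knn1",
                 "subspace_discriminant_ensemble")) {
    fit <- fit_classifier(classifier_spec(kind),
                          unclass(red)[tr, ], y[tr])
    acc <- mean(as.character(predict(fit, unclass(red)[te, ])) ==
                  as.character(y[te]))
    null_acc <- withr::with_seed(30, vapply(1:20, function(i) {
      yp <- sample(y[tr])
      fp <- fit_classifier(classifier_spec(kind), unclass(red)[tr, ], yp)
      mean(as.character(predict(fp, unclass(red)[te, ])) ==
             as.character(y[te]))
    }, numeric(1)))
    # chance level (1/5) plus three standard deviations of the null
    expect_gt(acc, 0.2 + 3 * stats::sd(null_acc))
  }
})
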