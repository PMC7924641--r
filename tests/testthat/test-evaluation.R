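test_that("repeated stratified folds partition every repeat and stratify within one", {
  y <- rep(c("a", "b", "c", "d", "e"), each = 20)
  cfg <- cv_config(5L, 5L, base_seed = 17L)
  folds <- split_folds(y, cfg)
  expect_length(folds, 5L)
  for (assign in folds) {
    expect_identical(sort(unique(assign)), 1:5)
    expect_equal(as.vector(table(assign)), rep(20L, 5L))   # folds of 20
    # class proportions per fold within +-1 of global (here: exactly 4)
    tab <- table(assign, y)
    expect_true(all(abs(tab - 4) <= 1))
  }
  # 5 x 5 = 25 train/test pairs
  expect_identical(sum(vapply(folds, function(a) length(unique(a)),
                              integer(1))), 25L)
  # repeats differ but are individually reproducible
  expect_false(identical(folds[[1]], folds[[2]]))
  again <- split_folds(y, cv_config(5L, 5L, base_seed = 17L))
  expect_identical(folds, again)
  expect_error(split_folds(rep(c("a", "b"), c(3, 50)), cfg), "'a'")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # direct substitution: TP=3 FN=2 TN=4 FP=1
  m <- compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  # the all-correct binary case: every metric is 1
  perfect <- compute_metrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, precision = 1))
  # zero denominator: reported as NaN, flagged, never silently zero
  und <- compute_metrics(tp = 0, fp = 0, tn = 7, fn = 3)
  expect_true(is.nan(und$precision))
  expect_identical(attr(und, "n_undefined"), 1L)
  expect_error(compute_metrics(tp = -1, fp = 0, tn = 0, fn = 0),
               "non-negative")
})

test_that("confusion counts decompose one-vs-rest and sum to the total", {
  cm <- matrix(c(5, 1, 0,
                 2, 6, 1,
                 0, 0, 5), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  counts <- confusion_counts(cm)
  expect_identical(counts$tp, c(5L, 6L, 5L))
  expect_identical(counts$fp, c(2L, 1L, 1L))
  expect_identical(counts$fn, c(1L, 3L, 0L))
  expect_true(all(counts$tp + counts$fp + counts$tn + counts$fn == sum(cm)))
  s <- histocascade:::summarize_confusion(cm)
  expect_equal(s$accuracy, 16 / 20)
  expect_equal(s$sensitivity, mean(c(5 / 6, 6 / 9, 5 / 5)))
})

test_that("scenario reports average per-fold metrics exactly and audit leakage", {
  set <- small_fixture()
  rep4 <- run_scenario("IV", set,
                       classifiers = list(classifier_spec("lda"),
                                          classifier_spec("knn1")),
                       n_components = 10L,
                       cv = cv_config(4L, 2L, base_seed = 5L), seed = 31L)
  expect_s3_class(rep4, "hc_cv")
  expect_named(rep4$entries, c("lda", "knn1"))
  for (e in rep4$entries) {
    expect_length(e$folds, 8L)
    expect_equal(e$mean_accuracy, mean(e$fold_accuracies), tolerance = 1e-12)
    widths <- vapply(e$folds, `[[`, numeric(1), "feature_width")
    expect_true(all(widths == 10L))
  }
  expect_true(audit_leakage(rep4))
  # a forged lineage entry must trip the audit
  forged <- rep4
  forged$entries$lda$folds[[1]]$fit_lineage[[2]]$ids <-
    c(forged$entries$lda$folds[[1]]$fit_lineage[[2]]$ids,
      forged$entries$lda$folds[[1]]$test_ids[1])
  forged$entries$lda$folds[[1]]$fit_lineage[[2]]$parents <-
    c(forged$entries$lda$folds[[1]]$fit_lineage[[2]]$parents, NA)
  expect_error(audit_leakage(forged), "leakage")
})

test_that("scenario III keeps the per-backbone stf widths in every fold", {
  set <- small_fixture()
  rep3 <- run_scenario("III", set, backbones = "densenet201",
                       classifiers = list(classifier_spec("lda")),
                       cv = cv_config(4L, 1L, base_seed = 5L), seed = 31L)
  widths <- vapply(rep3$entries[["densenet201.lda"]]$folds, `[[`,
                   numeric(1), "feature_width")
  expect_true(all(widths == 1010L))
})

test_that("scenario II enumerates backbone x classifier entries", {
  set <- small_fixture()
  specs <- lapply(c("lda", "knn1", "subspace_discriminant_ensemble"),
                  classifier_spec)
  rep2 <- run_scenario("II", set, backbones = c("resnet50", "mobilenet"),
                       classifiers = specs,
                       cv = cv_config(4L, 1L, base_seed = 5L), seed = 31L)
  expect_length(rep2$entries, 6L)
  expect_true(all(grepl("^(resnet50|mobilenet)\\.", names(rep2$entries))))
  expect_true(audit_leakage(rep2))
  s <- summary(rep2)
  expect_identical(nrow(s), 6L)
  expect_true(all(s$mean_accuracy >= 0 & s$mean_accuracy <= 1))
})

test_that("scenario I fine-tunes per fold and stays leakage-free", {
  set <- small_fixture()
  keep <- which(set$labels %in% 1:4)
  four <- image_set(set$images[keep], set$labels[keep],
                    set$class_names[1:4], sample_ids = set$sample_ids[keep])
  rep1 <- run_scenario("I", four, backbones = "mobilenet",
                       cv = cv_config(4L, 1L, base_seed = 5L),
                       train_cfg = train_config(epochs = 10L), seed = 31L)
  expect_named(rep1$entries, "mobilenet")
  expect_length(rep1$entries$mobilenet$folds, 4L)
  expect_true(audit_leakage(rep1))
})

test_that("training-fold augmentation feeds only training lineage into the fit", {
  set <- small_fixture()
  sub <- subset_image_set(set, which(set$labels %in% 1:2))
  pol <- augmentation_policy(per_image_copies = 1L, seed = 3L)
  repa <- run_scenario("II", sub, backbones = "mobilenet",
                       classifiers = list(classifier_spec("lda")),
                       cv = cv_config(4L, 1L, base_seed = 5L),
                       augmentation = pol, seed = 31L)
  expect_true(audit_leakage(repa))
  # augmented copies really were used for fitting
  lin <- repa$entries[["mobilenet.lda"]]$folds[[1]]$fit_lineage
  cls <- lin[[length(lin)]]
  expect_true(any(grepl("#aug", cls$ids)))
})

test_that("cross-validation configs are validated", {
  expect_error(cv_config(k = 1L), "k")
  expect_error(cv_config(repeats = 0L), "repeats")
  expect_error(run_scenario("I", small_fixture(),
                            cv = cv_config(4L, 1L)), "2 or 4")
})
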