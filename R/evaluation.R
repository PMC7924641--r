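#' Cross-validation configuration
#'
#' Repeated stratified k-fold cross-validation; study defaults are 5 folds
#' repeated 5 times. Repeat `r` derives its fold seed as `base_seed + r`,
#' so any single repeat is reproducible in isolation.
#'
#' @param k folds per repeat (>= 2).
#' @param repeats number of repeats (>= 1).
#' @param stratified preserve class proportions per fold.
#' @param base_seed integer seed.
#' @return object of class `"cv_config"`.
#' @export
cv_config <- function(k = 5L, repeats = 5L, stratified = TRUE, base_seed = 1L) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  structure(list(k = k, repeats = repeats, stratified = isTRUE(stratified),
                 base_seed = as.integer(base_seed)),
            class = "cv_config")
}

#' Assign repeated stratified folds
#'
#' Per repeat, partitions the samples into `k` folds. Under stratification
#' each class is shuffled and dealt round-robin, so per-fold class counts
#' differ from exact proportionality by at most one sample. Every sample
#' lands in exactly one test fold per repeat.
#'
#' @param labels class labels (any type coercible to factor).
#' @param cfg a [cv_config()].
#' @return list of length `repeats`; each element an integer vector of fold
#'   ids (1..k) per sample.
#' @export
split_folds <- function(labels, cfg = cv_config()) {
  stopifnot(inherits(cfg, "cv_config"))
  y <- factor(labels)
  counts <- table(y)
  if (cfg$stratified && any(counts < cfg$k)) {
    bad <- names(counts)[counts < cfg$k]
    stop(sprintf("class '%s' has fewer than k = %d members",
                 bad[1], cfg$k), call. = FALSE)
  }
  if (!cfg$stratified && length(y) < cfg$k) {
    stop("fewer samples than folds", call. = FALSE)
  }
  lapply(seq_len(cfg$repeats), function(r) {
    withr::with_seed(cfg$base_seed + r, {
      assign <- integer(length(y))
      if (cfg$stratified) {
        for (lev in levels(y)) {
          idx <- which(y == lev)
          assign[idx[sample.int(length(idx))]] <-
            rep_len(sample.int(cfg$k), length(idx))
        }
      } else {
        assign[sample.int(length(y))] <- rep_len(sample.int(cfg$k), length(y))
      }
      assign
    })
  })
}

#' Per-class confusion counts from a confusion matrix
#'
#' One-vs-rest decomposition of a square confusion matrix (rows = truth,
#' columns = prediction) into per-class TP, FP, TN, FN. For every class the
#' four counts sum to the total number of test samples.
#'
#' @param cm square confusion matrix, rows = truth, columns = predicted,
#'   identical dimnames order.
#' @return data.frame with columns `class`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  data.frame(class = colnames(cm) %||% as.character(seq_len(nrow(cm))),
             tp = as.integer(tp), fp = as.integer(fp),
             tn = as.integer(tn), fn = as.integer(fn),
             row.names = NULL)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and precision `TP/(TP+FP)`, vectorised over classes. A zero
#' denominator yields `NaN` (reported, never silently zero); the return
#' value's `"n_undefined"` attribute counts such entries.
#'
#' @param tp,fp,tn,fn non-negative integer counts, or a single data.frame
#'   as produced by [confusion_counts()] passed as `tp`.
#' @return data.frame with one row per class and columns `accuracy`,
#'   `sensitivity`, `specificity`, `precision`.
#' @export
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    df <- tp; tp <- df$tp; fp <- df$fp; tn <- df$tn; fn <- df$fn
  }
  if (any(c(tp, fp, tn, fn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NaN)
  out <- data.frame(
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp)
  )
  attr(out, "n_undefined") <- sum(is.nan(as.matrix(out)))
  out
}

# macro (one-vs-rest) summary of a confusion matrix; overall accuracy is
# trace/total, macro metrics average the defined per-class values
summarize_confusion <- function(cm) {
  counts <- confusion_counts(cm)
  m <- compute_metrics(counts)
  macro <- function(v) mean(v[!is.nan(v)])
  list(accuracy = sum(diag(as.matrix(cm))) / sum(cm),
       sensitivity = macro(m$sensitivity),
       specificity = macro(m$specificity),
       precision = macro(m$precision),
       per_class = cbind(counts, m))
}

#' Audit a cross-validation report for train/test leakage
#'
#' Verifies that no test-fold sample identifier — nor any augmented copy
#' derived from one — appears among the fitting identifiers recorded by any
#' fitted component (reduction, classifier, fine-tuned head) of its own
#' fold.
#'
#' @param report an `"hc_cv"` report from [run_scenario()].
#' @return `TRUE` invisibly; errors with the offending ids otherwise.
#' @export
audit_leakage <- function(report) {
  stopifnot(inherits(report, "hc_cv"))
  for (entry in report$entries) {
    for (fr in entry$folds) {
      test_ids <- fr$test_ids
      for (comp in fr$fit_lineage) {
        # an augmented copy leaks its source: compare on the source id
        src <- ifelse(is.na(comp$parents), comp$ids, comp$parents)
        bad <- intersect(src, test_ids)
        if (length(bad)) {
          stop("leakage: test sample(s) in fitted component '",
               comp$component, "': ", paste(bad, collapse = ", "),
               call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' Run one evaluation scenario under repeated stratified cross-validation
#'
#' The four cascade configurations:
#' * **I** — fine-tune each backbone's head on the training fold and
#'   predict end-to-end; one report entry per backbone.
#' * **II** — global-average-pooling (spatial) features per backbone, fed
#'   to each classical classifier; entries are backbone x classifier.
#' * **III** — level-1 wavelet detail ("stf") features per backbone, fed to
#'   each classifier.
#' * **IV** — the three stf sets fused and reduced (DCT truncation or PCA,
#'   fitted on the training fold only) before classification; entries per
#'   classifier.
#'
#' Backbone weights are frozen at their seeded initialisation, so feature
#' extraction is an unsupervised deterministic transform and is computed
#' once for all folds; every supervised fit (head fine-tuning, reduction,
#' classifier, standardisation) sees training-fold rows only. When an
#' [augmentation_policy()] is supplied, augmented copies of the
#' training-fold images are generated inside each fold and never derived
#' from test images.
#'
#' @param scenario `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param data an [image_set()], already resized to the working size.
#' @param backbones character vector of backbone names.
#' @param classifiers list of [classifier_spec()] objects (scenarios
#'   II--IV).
#' @param wavelet a [wavelet_filter()] (scenarios III and IV).
#' @param reduction `"pca"` or `"dct"` (scenario IV).
#' @param n_components retained dimension for scenario IV; or `"search"`
#'   to run [sequential_forward_search()] on each training fold with
#'   `search_grid`.
#' @param search_grid candidate grid used when `n_components = "search"`.
#' @param cv a [cv_config()].
#' @param train_cfg a [train_config()] (scenario I).
#' @param augmentation optional [augmentation_policy()] applied to training
#'   folds only.
#' @param seed integer seed from which per-backbone weight seeds derive.
#' @return an `"hc_cv"` report; see [summary.hc_cv()].
#' @export
run_scenario <- function(scenario = c("IV", "I", "II", "III"), data,
                         backbones = c("resnet50", "densenet201", "mobilenet"),
                         classifiers = list(classifier_spec("lda")),
                         wavelet = dmey_filter(),
                         reduction = c("pca", "dct"),
                         n_components = 25L,
                         search_grid = NULL,
                         cv = cv_config(),
                         train_cfg = train_config(),
                         augmentation = NULL,
                         seed = 1L) {
  scenario <- match.arg(scenario)
  reduction <- match.arg(reduction)
  stopifnot(inherits(data, "image_set"))
  if (inherits(classifiers, "classifier_spec")) classifiers <- list(classifiers)
  t0 <- proc.time()[["elapsed"]]
  num_classes <- length(data$class_names)
  if (scenario == "I" && !num_classes %in% c(2L, 4L)) {
    stop("scenario I requires 2 or 4 classes (the backbone head widths)",
         call. = FALSE)
  }
  folds <- split_folds(data$labels, cv)
  y <- factor(data$class_names[data$labels], levels = data$class_names)

  models <- NULL; feat_sets <- NULL
  if (scenario != "I") {
    models <- lapply(seq_along(backbones), function(b)
      build_backbone(backbone_spec(backbones[b],
                                   num_classes = if (num_classes %in% c(2L, 4L))
                                     num_classes else 2L),
                     seed = seed + b))
    feat_sets <- lapply(models, extract_gap_features, data = data)
    if (scenario %in% c("III", "IV")) {
      feat_sets <- lapply(feat_sets, stf_transform, filt = wavelet)
    }
    if (scenario == "IV") {
      feat_sets <- list(fused = concat_fused(feat_sets))
    } else {
      names(feat_sets) <- backbones
    }
  }

  entries <- list()
  if (scenario == "I") {
    for (b in seq_along(backbones)) {
      entries[[backbones[b]]] <- cv_end_to_end(
        data, folds, cv, backbones[b], num_classes, train_cfg,
        augmentation, seed + b)
    }
  } else {
    cls_names <- vapply(classifiers, function(s) s$kind, character(1))
    for (fs in names(feat_sets)) {
      for (ci in seq_along(classifiers)) {
        key <- if (scenario == "IV") cls_names[ci]
               else paste(fs, cls_names[ci], sep = ".")
        entries[[key]] <- cv_features(
          feat_sets[[fs]], y, data, folds, cv, classifiers[[ci]],
          fuse_reduce = (scenario == "IV"), reduction = reduction,
          n_components = n_components, search_grid = search_grid,
          models = models, wavelet = wavelet, scenario = scenario,
          augmentation = augmentation)
      }
    }
  }
  structure(
    list(scenario = scenario, level = data$level,
         class_names = data$class_names, cv = cv, entries = entries,
         config = list(backbones = backbones, reduction = reduction,
                       n_components = n_components, seed = seed,
                       augmented = !is.null(augmentation)),
         elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "hc_cv"
  )
}

# scenario I inner loop: per-fold head fine-tuning + end-to-end prediction
cv_end_to_end <- function(data, folds, cv, backbone, num_classes, train_cfg,
                          augmentation, seed) {
  fold_records <- list()
  lev <- data$class_names
  for (r in seq_len(cv$repeats)) {
    for (fold in seq_len(cv$k)) {
      tr <- which(folds[[r]] != fold); te <- which(folds[[r]] == fold)
      train_set <- subset_image_set(data, tr)
      if (!is.null(augmentation)) {
        train_set <- augment_images(train_set, augmentation)
      }
      model <- build_backbone(backbone_spec(backbone,
                                            num_classes = num_classes),
                              seed = seed)
      model <- fine_tune(model, train_set, train_cfg)
      pred <- predict_end_to_end(model, subset_image_set(data, te))
      cm <- table(truth = factor(lev[data$labels[te]], levels = lev),
                  predicted = factor(lev[pred], levels = lev))
      fold_records[[length(fold_records) + 1L]] <- list(
        rep = r, fold = fold,
        accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
        test_ids = data$sample_ids[te],
        fit_lineage = list(list(component = "fine_tuned_head",
                                ids = train_set$sample_ids,
                                parents = train_set$parents)))
    }
  }
  aggregate_entry(fold_records, lev)
}

# scenarios II-IV inner loop over precomputed (frozen-weight) features
cv_features <- function(feats, y, data, folds, cv, spec, fuse_reduce,
                        reduction, n_components, search_grid, models,
                        wavelet, scenario, augmentation) {
  X <- unclass(feats)
  lev <- levels(y)
  fold_records <- list()
  for (r in seq_len(cv$repeats)) {
    for (fold in seq_len(cv$k)) {
      tr <- which(folds[[r]] != fold); te <- which(folds[[r]] == fold)
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      ids_tr <- data$sample_ids[tr]; par_tr <- data$parents[tr]
      if (!is.null(augmentation)) {
        aug <- augmented_features(data, tr, augmentation, models, wavelet,
                                  scenario, fuse_reduce)
        Xtr <- rbind(Xtr, aug$x)
        ytr <- factor(c(as.character(ytr), as.character(aug$y)), levels = lev)
        ids_tr <- c(ids_tr, aug$ids)
        par_tr <- c(par_tr, aug$parents)
      }
      rownames(Xtr) <- ids_tr
      lineage <- list()
      if (fuse_reduce) {
        n_use <- n_components
        if (identical(n_components, "search")) {
          grid <- search_grid %||% default_search_grid(reduction, ncol(Xtr),
                                                       length(tr))
          sfs <- sequential_forward_search(
            Xtr, ytr, method = reduction, candidates = grid,
            cv = cv_config(cv$k, 1L, cv$stratified, cv$base_seed),
            classifier = spec)
          n_use <- sfs$chosen
        }
        red <- if (reduction == "pca") fit_pca(Xtr, n_use)
               else reduce_dct(Xtr, n_use)$model
        lineage[[length(lineage) + 1L]] <- list(
          component = paste0("reduction_", reduction),
          ids = if (reduction == "pca") ids_tr else character(0),
          parents = if (reduction == "pca") par_tr else character(0))
        Xte <- unclass(apply_reduction(red, X[te, , drop = FALSE]))
        Xtr <- unclass(apply_reduction(red, Xtr))
      } else {
        Xte <- X[te, , drop = FALSE]
      }
      rownames(Xtr) <- ids_tr
      fit <- fit_classifier(spec, Xtr, ytr)
      lineage[[length(lineage) + 1L]] <- list(component = spec$kind,
                                              ids = ids_tr, parents = par_tr)
      pred <- predict(fit, Xte)
      cm <- table(truth = y[te], predicted = factor(pred, levels = lev))
      fold_records[[length(fold_records) + 1L]] <- list(
        rep = r, fold = fold,
        accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
        feature_width = ncol(Xte),
        test_ids = data$sample_ids[te],
        fit_lineage = lineage)
    }
  }
  aggregate_entry(fold_records, lev)
}

# features of augmented copies of the training-fold images
augmented_features <- function(data, tr, augmentation, models, wavelet,
                               scenario, fuse_reduce) {
  train_set <- subset_image_set(data, tr)
  aug_all <- augment_images(train_set, augmentation)
  new <- which(!is.na(aug_all$parents))
  aug_set <- subset_image_set(aug_all, new)
  fs <- lapply(models, extract_gap_features, data = aug_set)
  if (scenario %in% c("III", "IV")) {
    fs <- lapply(fs, stf_transform, filt = wavelet)
  }
  xm <- if (fuse_reduce) unclass(concat_fused(fs)) else unclass(fs[[1]])
  list(x = xm,
       y = factor(aug_set$class_names[aug_set$labels],
                  levels = aug_set$class_names),
       ids = aug_set$sample_ids, parents = aug_set$parents)
}

default_search_grid <- function(reduction, width, n_train) {
  if (reduction == "dct") {
    g <- seq(100L, min(width, 2700L), by = 100L)
  } else {
    g <- c(2L, 5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L, 95L)
    g <- g[g <= min(width, n_train - 1L)]
  }
  g
}

# aggregate fold records: mean of per-fold metrics + pooled confusion
aggregate_entry <- function(fold_records, lev) {
  accs <- vapply(fold_records, `[[`, numeric(1), "accuracy")
  pooled <- Reduce(`+`, lapply(fold_records, `[[`, "confusion"))
  per_fold <- lapply(fold_records, function(fr) summarize_confusion(fr$confusion))
  mfold <- function(field) mean(vapply(per_fold, `[[`, numeric(1), field))
  list(folds = fold_records,
       mean_accuracy = mean(accs),
       sd_accuracy = stats::sd(accs),
       mean_sensitivity = mfold("sensitivity"),
       mean_specificity = mfold("specificity"),
       mean_precision = mfold("precision"),
       pooled = summarize_confusion(pooled),
       fold_accuracies = accs)
}

#' @export
print.hc_cv <- function(x, ...) {
  cat(sprintf("<hc_cv> scenario %s, %s level, %d-fold x %d repeats\n",
              x$scenario, x$level, x$cv$k, x$cv$repeats))
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    cat(sprintf("  %-40s accuracy %.4f (sd %.4f)\n",
                nm, e$mean_accuracy, e$sd_accuracy))
  }
  invisible(x)
}

#' Summarise a cross-validation report
#'
#' @param object an `"hc_cv"` report.
#' @param ... unused.
#' @return data.frame with one row per report entry: mean and sd of the
#'   per-fold accuracy and the macro-averaged sensitivity, specificity and
#'   precision.
#' @export
summary.hc_cv <- function(object, ...) {
  do.call(rbind, lapply(names(object$entries), function(nm) {
    e <- object$entries[[nm]]
    data.frame(entry = nm, mean_accuracy = e$mean_accuracy,
               sd_accuracy = e$sd_accuracy,
               sensitivity = e$mean_sensitivity,
               specificity = e$mean_specificity,
               precision = e$mean_precision,
               row.names = NULL)
  }))
}

#' Plot per-fold accuracies of a cross-validation report
#'
#' Strip chart of the per-fold accuracies per entry with the mean marked.
#'
#' @param x an `"hc_cv"` report.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.hc_cv <- function(x, ...) {
  accs <- lapply(x$entries, `[[`, "fold_accuracies")
  graphics::stripchart(accs, vertical = TRUE, method = "jitter",
                       pch = 1, ylab = "fold accuracy",
                       group.names = names(accs), las = 2, ...)
  means <- vapply(accs, mean, numeric(1))
  graphics::points(seq_along(means), means, pch = 19, col = 2)
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits `report.json` (summary + per-fold accuracies + config echo) and
#' one CSV of pooled confusion counts per entry.
#'
#' @param report an `"hc_cv"` report.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "hc_cv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(scenario = report$scenario, level = report$level,
             k = report$cv$k, repeats = report$cv$repeats,
             config = report$config,
             entries = lapply(report$entries, function(e) {
               list(mean_accuracy = e$mean_accuracy,
                    sd_accuracy = e$sd_accuracy,
                    sensitivity = e$mean_sensitivity,
                    specificity = e$mean_specificity,
                    precision = e$mean_precision,
                    fold_accuracies = e$fold_accuracies)
             }))
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report$entries)) {
    utils::write.csv(as.data.frame(report$entries[[nm]]$pooled$per_class),
                     file.path(dir, paste0("confusion_", gsub("\\W", "_", nm),
                                           ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
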