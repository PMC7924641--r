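#' Fit the cascaded histopathology classifier
#'
#' The single fitting entry point: embeds each training image with the
#' configured convolutional backbones read out at the global-average-pooling
#' layer, converts each embedding to its single-level discrete Meyer
#' wavelet detail coefficients, fuses the per-backbone coefficient sets,
#' reduces the fused matrix with DCT truncation or PCA, and fits the chosen
#' classical classifier on the reduced training features. The returned
#' object predicts new images end-to-end with [predict.histocascade()].
#'
#' `scenario` selects how much of the cascade is used, matching the four
#' evaluation configurations of [run_scenario()]: `"I"` fine-tunes a single
#' backbone head and classifies with its softmax layer; `"II"` classifies
#' spatial features of a single backbone; `"III"` classifies that
#' backbone's wavelet-detail features; `"IV"` (default) runs the full
#' fusion cascade over all three backbones.
#'
#' @param data an [image_set()] of training images, resized to a common
#'   size.
#' @param scenario `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param backbones backbone names; scenarios I--III use the first one.
#' @param wavelet a [wavelet_filter()].
#' @param reduction `"pca"` or `"dct"` (scenario IV).
#' @param n_components retained dimension for scenario IV.
#' @param classifier a [classifier_spec()] (scenarios II--IV).
#' @param train_cfg a [train_config()] (scenario I).
#' @param seed integer seed; per-backbone weight seeds derive from it.
#' @return object of class `"histocascade"`.
#' @examples
#' set <- generate_fixture(fixture_spec(n_per_class = 6, image_size = c(64, 64)))
#' fit <- histocascade(set, n_components = 10)
#' table(predicted = predict(fit, set), truth = set$class_names[set$labels])
#' @export
histocascade <- function(data, scenario = c("IV", "I", "II", "III"),
                         backbones = c("resnet50", "densenet201", "mobilenet"),
                         wavelet = dmey_filter(),
                         reduction = c("pca", "dct"),
                         n_components = 25L,
                         classifier = classifier_spec("lda"),
                         train_cfg = train_config(),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  reduction <- match.arg(reduction)
  stopifnot(inherits(data, "image_set"))
  num_classes <- length(data$class_names)
  if (scenario != "IV") backbones <- backbones[1]
  models <- lapply(seq_along(backbones), function(b)
    build_backbone(backbone_spec(backbones[b],
                                 num_classes = if (num_classes %in% c(2L, 4L))
                                   num_classes else 2L),
                   seed = seed + b))
  names(models) <- backbones
  red <- NULL; fit <- NULL
  if (scenario == "I") {
    if (!num_classes %in% c(2L, 4L)) {
      stop("scenario I requires 2 or 4 classes", call. = FALSE)
    }
    models[[1]] <- fine_tune(models[[1]], data, train_cfg)
  } else {
    feats <- lapply(models, extract_gap_features, data = data)
    if (scenario %in% c("III", "IV")) {
      feats <- lapply(feats, stf_transform, filt = wavelet)
    }
    X <- if (scenario == "IV") concat_fused(feats) else feats[[1]]
    if (scenario == "IV") {
      red <- if (reduction == "pca") fit_pca(X, n_components)
             else reduce_dct(X, n_components)$model
      X <- apply_reduction(red, X)
    }
    y <- factor(data$class_names[data$labels], levels = data$class_names)
    fit <- fit_classifier(classifier, X, y)
  }
  structure(
    list(scenario = scenario, models = models, wavelet = wavelet,
         reduction = red, classifier = fit, class_names = data$class_names,
         level = data$level, seed = as.integer(seed),
         n_train = length(data$images)),
    class = "histocascade"
  )
}

#' Predict classes for new images
#'
#' Runs the fitted cascade on a new [image_set()] (images must match the
#' training size).
#'
#' @param object a fitted [histocascade()] model.
#' @param newdata an [image_set()].
#' @param ... unused.
#' @return factor of predicted class names.
#' @export
predict.histocascade <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "image_set"))
  if (object$scenario == "I") {
    idx <- predict_end_to_end(object$models[[1]], newdata)
    return(factor(object$class_names[idx], levels = object$class_names))
  }
  feats <- lapply(object$models, extract_gap_features, data = newdata)
  if (object$scenario %in% c("III", "IV")) {
    feats <- lapply(feats, stf_transform, filt = object$wavelet)
  }
  X <- if (object$scenario == "IV") concat_fused(feats) else feats[[1]]
  if (!is.null(object$reduction)) X <- apply_reduction(object$reduction, X)
  factor(as.character(predict(object$classifier, X)),
         levels = object$class_names)
}

#' @export
print.histocascade <- function(x, ...) {
  cat(sprintf("<histocascade> scenario %s, %s level, %d classes\n",
              x$scenario, x$level, length(x$class_names)))
  cat("  backbones:", paste(names(x$models), collapse = ", "), "\n")
  if (!is.null(x$reduction)) {
    cat(sprintf("  reduction: %s, %d retained of %d\n",
                x$reduction$method, x$reduction$retained,
                x$reduction$input_dim))
  }
  if (!is.null(x$classifier)) {
    cat("  classifier:", x$classifier$spec$kind, "\n")
  }
  invisible(x)
}

#' @export
summary.histocascade <- function(object, ...) {
  print(object)
  if (!is.null(object$reduction) && object$reduction$method == "pca") {
    ev <- object$reduction$sdev^2
    cat(sprintf("  PCA explained variance (top 5): %s\n",
                paste(signif(utils::head(ev, 5), 3), collapse = ", ")))
  }
  cat(sprintf("  fitted on %d images\n", object$n_train))
  invisible(object)
}

#' Write / read a feature table
#'
#' Lossless plain-text serialisation of a [feature_matrix()]: a CSV with
#' the sample id in the first column and `%.17g`-formatted values (17
#' significant digits round-trip IEEE doubles exactly), plus provenance
#' and backbone recorded on a comment line.
#'
#' @param feats a [feature_matrix()].
#' @param path output file.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   the reconstructed [feature_matrix()].
#' @export
write_features <- function(feats, path) {
  x <- as_feature_matrix(feats)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance=%s backbone=%s", attr(x, "provenance"),
                     attr(x, "backbone")), con)
  writeLines(paste(c("sample_id", sprintf("f%d", seq_len(ncol(x)))),
                   collapse = ","), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = ","),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("provenance=(\\S+) backbone=(\\S+)", header))[[1]]
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        colClasses = "character")
  m <- matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])), nrow = nrow(df))
  feature_matrix(m, provenance = meta[2],
                 backbone = if (meta[3] == "NA") NA_character_ else meta[3],
                 sample_ids = df[[1]])
}
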