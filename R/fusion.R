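#' Concatenate wavelet-detail feature sets across backbones
#'
#' Column-wise concatenation of the per-backbone spatial-time-frequency
#' feature matrices in the fixed order resnet50, densenet201, mobilenet
#' (matrices carrying backbone records are reordered canonically; otherwise
#' the given order is kept). All sets must share row count and row order.
#' With the packaged 102-tap discrete Meyer filter the three widths
#' 1074 + 1010 + 690 fuse to 2774 columns.
#'
#' @param stf_sets list of [feature_matrix()] objects with identical
#'   `sample_ids`.
#' @return a [feature_matrix()] with provenance `"fused"`.
#' @export
concat_fused <- function(stf_sets) {
  stopifnot(is.list(stf_sets), length(stf_sets) >= 1L)
  lapply(stf_sets, as_feature_matrix)
  ids <- rownames(stf_sets[[1]])
  for (s in stf_sets[-1]) {
    if (!identical(rownames(s), ids)) {
      stop("feature sets disagree on row order (sample_ids)", call. = FALSE)
    }
  }
  canon <- c("resnet50", "densenet201", "mobilenet")
  backs <- vapply(stf_sets, function(s) attr(s, "backbone") %||% NA_character_,
                  character(1))
  if (!anyNA(backs) && setequal(backs, canon[seq_along(backs)])) {
    stf_sets <- stf_sets[order(match(backs, canon))]
  }
  if (length(stf_sets) == 1L) return(stf_sets[[1]])
  fused <- do.call(cbind, lapply(stf_sets, unclass))
  feature_matrix(fused, provenance = "fused", sample_ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# first `rows` rows of the orthonormal DCT-II matrix of size n
dct_matrix <- function(n, rows = n) {
  k <- seq_len(rows) - 1
  j <- seq_len(n) - 1
  C <- sqrt(2 / n) * cos(outer(k, j + 0.5) * pi / n)
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Orthonormal DCT-II of each matrix row
#'
#' Applies the type-II discrete cosine transform with orthonormal scaling
#' to every row independently. The transform is unitary: per-row energy is
#' preserved and `dct_rows(x, inverse = TRUE)` undoes it.
#'
#' @param x numeric matrix (or [feature_matrix()]), rows = samples.
#' @param inverse apply the inverse (DCT-III) instead.
#' @return matrix of the same shape.
#' @export
dct_rows <- function(x, inverse = FALSE) {
  xm <- if (inherits(x, "feature_matrix")) unclass(x) else as.matrix(x)
  C <- dct_matrix(ncol(xm))
  out <- if (inverse) xm %*% C else xm %*% t(C)
  dimnames(out) <- dimnames(xm)
  out
}

#' Fitted reduction model (DCT truncation or PCA)
#'
#' @param method `"dct"` or `"pca"`.
#' @param retained retained dimension.
#' @param input_dim expected input width.
#' @param center,rotation PCA mean vector and component matrix (columns are
#'   orthonormal components); `NULL` for DCT.
#' @param sdev PCA component standard deviations (explained variances are
#'   their squares, non-increasing).
#' @param fit_sample_ids identifiers of the fitting rows (empty for DCT,
#'   which needs no fit); used by the leakage audit.
#' @return object of class `"reduction_model"`.
#' @keywords internal
new_reduction_model <- function(method, retained, input_dim, center = NULL,
                                rotation = NULL, sdev = NULL,
                                fit_sample_ids = character(0)) {
  structure(
    list(method = method, retained = as.integer(retained),
         input_dim = as.integer(input_dim), center = center,
         rotation = rotation, sdev = sdev,
         fit_sample_ids = fit_sample_ids),
    class = "reduction_model"
  )
}

#' Reduce features by DCT truncation
#'
#' Transforms each row with the orthonormal DCT-II and keeps the first `n`
#' (lowest-frequency) coefficients.
#'
#' @param x a [feature_matrix()] or numeric matrix.
#' @param n retained coefficient count, `1 <= n <= ncol(x)`.
#' @return `list(scores, model)` where `scores` is an `nrow(x) x n`
#'   [feature_matrix()] and `model` a `"reduction_model"`.
#' @export
reduce_dct <- function(x, n) {
  xm <- if (inherits(x, "feature_matrix")) unclass(x) else as.matrix(x)
  n <- as.integer(n)
  if (n < 1L || n > ncol(xm)) {
    stop("retained dimension n out of range [1, ncol(x)]", call. = FALSE)
  }
  model <- new_reduction_model("dct", n, ncol(xm))
  list(scores = apply_reduction(model, x), model = model)
}

#' Fit a PCA reduction on training rows
#'
#' Centres by the training mean and takes the top-`n` eigenvectors of the
#' training covariance (via singular value decomposition). No variance
#' scaling is applied.
#'
#' @param x_train a [feature_matrix()] or numeric matrix of training rows.
#' @param n component count, `1 <= n <= min(nrow - 1, ncol)`.
#' @return a `"reduction_model"` recording mean, components, and the
#'   fitting rows' identifiers.
#' @export
fit_pca <- function(x_train, n) {
  xm <- if (inherits(x_train, "feature_matrix")) unclass(x_train)
        else as.matrix(x_train)
  n <- as.integer(n)
  if (n < 1L || n > min(nrow(xm) - 1L, ncol(xm))) {
    stop("component count n out of range [1, min(nrow - 1, ncol)]",
         call. = FALSE)
  }
  pr <- stats::prcomp(xm, center = TRUE, scale. = FALSE, rank. = n)
  new_reduction_model("pca", n, ncol(xm), center = pr$center,
                      rotation = pr$rotation, sdev = pr$sdev[seq_len(n)],
                      fit_sample_ids = rownames(xm) %||% character(0))
}

#' Apply a fitted reduction
#'
#' Deterministic projection: DCT-truncation or centre-and-project. Never
#' refits; applying a PCA model to new rows uses the training mean and
#' components as fitted.
#'
#' @param model a `"reduction_model"` from [reduce_dct()] or [fit_pca()].
#' @param x matrix whose width equals the model's input dimension.
#' @return an `nrow(x) x retained` [feature_matrix()] with provenance
#'   `"reduced"`.
#' @export
apply_reduction <- function(model, x) {
  stopifnot(inherits(model, "reduction_model"))
  xm <- if (inherits(x, "feature_matrix")) unclass(x) else as.matrix(x)
  if (ncol(xm) != model$input_dim) {
    stop(sprintf("feature width %d does not match the model's input dim %d",
                 ncol(xm), model$input_dim), call. = FALSE)
  }
  scores <- if (model$method == "dct") {
    xm %*% t(dct_matrix(model$input_dim, rows = model$retained))
  } else {
    sweep(xm, 2L, model$center) %*% model$rotation
  }
  feature_matrix(scores, provenance = "reduced",
                 sample_ids = rownames(xm) %||% NULL)
}

#' Pick the smallest candidate achieving the maximum score
#'
#' The tie-break rule of the dimension search: candidates are considered in
#' increasing order and the smallest one attaining the maximum mean
#' accuracy wins (smaller representations are faster at equal accuracy).
#'
#' @param candidates increasing positive integers.
#' @param scores mean accuracy per candidate.
#' @return the chosen candidate.
#' @export
select_smallest_max <- function(candidates, scores) {
  stopifnot(length(candidates) == length(scores), length(candidates) >= 1L)
  ord <- order(candidates)
  candidates <- candidates[ord]; scores <- scores[ord]
  candidates[which.max(scores)]  # which.max returns the first (smallest) max
}

#' Sequential forward search over the retained dimension
#'
#' Evaluates an increasing grid of retained-dimension candidates: for each
#' candidate the reduction is fitted inside every cross-validation training
#' fold, the classifier is trained on the reduced training rows, and the
#' mean repeated-CV accuracy is recorded. Returns the full score profile
#' and the smallest candidate achieving the maximum (see
#' [select_smallest_max()]). Infeasible candidates (exceeding the fused
#' width, or for PCA the fold training row count minus one) are skipped
#' with a warning.
#'
#' @param x fused [feature_matrix()] (or numeric matrix).
#' @param labels integer or factor labels, one per row.
#' @param method `"pca"` or `"dct"`.
#' @param candidates positive integer grid (any order; evaluated sorted).
#' @param cv a [cv_config()]; defaults to 5-fold, 5 repeats.
#' @param classifier a [classifier_spec()]; defaults to LDA.
#' @return `list(grid = data.frame(candidate, mean_accuracy, sd_accuracy),
#'   chosen = <n>)`.
#' @export
sequential_forward_search <- function(x, labels, method = c("pca", "dct"),
                                      candidates,
                                      cv = cv_config(),
                                      classifier = classifier_spec("lda")) {
  method <- match.arg(method)
  xm <- if (inherits(x, "feature_matrix")) unclass(x) else as.matrix(x)
  labels <- as.integer(factor(labels))
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0L) stop("empty candidate grid", call. = FALSE)
  folds <- split_folds(labels, cv)
  max_n <- if (method == "pca") {
    min(ncol(xm), nrow(xm) - max(vapply(folds, function(f)
      max(tabulate(f, nbins = cv$k)), numeric(1))) - 1L)
  } else ncol(xm)
  feasible <- candidates <= max_n
  if (any(!feasible)) {
    warning(sprintf("skipping infeasible candidate(s): %s",
                    paste(candidates[!feasible], collapse = ", ")),
            call. = FALSE)
  }
  candidates <- candidates[feasible]
  if (length(candidates) == 0L) {
    stop("no feasible candidate in the grid", call. = FALSE)
  }
  nmax <- max(candidates)
  mean_acc <- sd_acc <- numeric(length(candidates))
  fold_scores <- matrix(NA_real_, nrow = length(candidates),
                        ncol = cv$repeats * cv$k)
  col <- 0L
  for (r in seq_len(cv$repeats)) {
    assign_r <- folds[[r]]
    for (fold in seq_len(cv$k)) {
      col <- col + 1L
      tr <- which(assign_r != fold); te <- which(assign_r == fold)
      # PCA components are nested, so fit once per fold at the largest
      # candidate and slice columns; DCT rows are nested likewise.
      red <- if (method == "pca") fit_pca(xm[tr, , drop = FALSE], nmax)
             else reduce_dct(xm[tr, , drop = FALSE], nmax)$model
      str_all <- unclass(apply_reduction(red, xm[tr, , drop = FALSE]))
      ste_all <- unclass(apply_reduction(red, xm[te, , drop = FALSE]))
      for (ci in seq_along(candidates)) {
        n <- candidates[ci]
        fit <- fit_classifier(classifier, str_all[, seq_len(n), drop = FALSE],
                              labels[tr])
        pred <- predict(fit, ste_all[, seq_len(n), drop = FALSE])
        fold_scores[ci, col] <- mean(as.integer(pred) == labels[te])
      }
    }
  }
  mean_acc <- rowMeans(fold_scores)
  sd_acc <- apply(fold_scores, 1L, stats::sd)
  grid <- data.frame(candidate = candidates, mean_accuracy = mean_acc,
                     sd_accuracy = sd_acc)
  list(grid = grid, chosen = select_smallest_max(candidates, mean_acc))
}
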