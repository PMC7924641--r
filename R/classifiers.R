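#' Classifier specification
#'
#' The five classifier configurations behind one uniform fit/predict
#' contract:
#' * `svm_linear` — linear-kernel SVM, cost 1, one-vs-one multiclass,
#'   features z-scored with training statistics inside the classifier.
#' * `svm_cubic` — polynomial kernel \eqn{(x \cdot x' / d + 1)^3}
#'   (degree 3, gamma `1/d`, coef0 1), cost 1, same standardisation.
#' * `knn1` — 1-nearest-neighbour, Euclidean metric; equidistant
#'   neighbours break to the lowest training index.
#' * `lda` — linear discriminant analysis with a pseudo-inverse pooled
#'   covariance, so it stays defined when features outnumber samples.
#' * `subspace_discriminant_ensemble` — random-subspace ensemble of
#'   discriminant learners (default 30 learners on feature subsets of size
#'   `min(1024, d)`), combined by averaging class posteriors.
#'
#' @param kind one of the five kinds above.
#' @param n_learners ensemble size (ensemble only).
#' @param subspace_dim subspace size before clamping to the feature count
#'   (ensemble only).
#' @param seed integer seed for the ensemble's subspace draws.
#' @return object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(kind = c("lda", "svm_linear", "svm_cubic", "knn1",
                                     "subspace_discriminant_ensemble"),
                            n_learners = 30L, subspace_dim = 1024L,
                            seed = 1L) {
  kind <- match.arg(kind)
  n_learners <- as.integer(n_learners)
  subspace_dim <- as.integer(subspace_dim)
  if (n_learners < 1L) stop("n_learners must be >= 1", call. = FALSE)
  if (subspace_dim < 1L) stop("subspace_dim must be >= 1", call. = FALSE)
  structure(
    list(kind = kind, n_learners = n_learners, subspace_dim = subspace_dim,
         k = 1L, metric = "euclidean", degree = 3L, cost = 1,
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param x_train numeric matrix or [feature_matrix()] of training rows.
#' @param y_train labels (coerced to factor); at least two classes must be
#'   present.
#' @return object of class `"hc_classifier"` supporting [predict()]. The
#'   fit records the training rows' sample identifiers for the leakage
#'   audit.
#' @export
fit_classifier <- function(spec, x_train, y_train) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- if (inherits(x_train, "feature_matrix")) unclass(x_train)
       else as.matrix(x_train)
  y <- factor(y_train)
  if (nlevels(droplevels(y)) < 2L) {
    stop("training fold contains a single class", call. = FALSE)
  }
  y <- droplevels(y)
  d <- ncol(X)
  model <- switch(
    spec$kind,
    svm_linear = fit_svm(X, y, kernel = "linear", spec = spec),
    svm_cubic = fit_svm(X, y, kernel = "polynomial", spec = spec),
    knn1 = list(x = X, y = y),
    lda = fit_lda_pinv(X, y),
    subspace_discriminant_ensemble = {
      dsub <- min(spec$subspace_dim, d)
      subsets <- withr::with_seed(spec$seed, lapply(
        seq_len(spec$n_learners), function(i) sort(sample.int(d, dsub))))
      learners <- lapply(subsets, function(s)
        fit_lda_pinv(X[, s, drop = FALSE], y))
      list(subsets = subsets, learners = learners)
    }
  )
  structure(
    list(spec = spec, model = model, levels = levels(y), dim = d,
         fit_sample_ids = rownames(X) %||% character(0)),
    class = "hc_classifier"
  )
}

fit_svm <- function(X, y, kernel, spec) {
  # standardise here (training statistics) rather than inside e1071 so
  # constant columns are handled deterministically
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  args <- list(x = Z, y = y, kernel = kernel, cost = spec$cost,
               scale = FALSE)
  if (kernel == "polynomial") {
    args <- c(args, list(degree = spec$degree, gamma = 1 / ncol(Z), coef0 = 1))
  }
  list(svm = do.call(e1071::svm, args), center = ctr, scale = scl)
}

# Linear discriminant analysis with a pseudo-inverse pooled covariance.
# Works in the span of the within-class scatter: whitened coordinates are
# z = (x - xbar) V diag(1/s), with V, s from the SVD of the centred
# within-class data; discriminant scores are computed there.
fit_lda_pinv <- function(X, y) {
  lev <- levels(y)
  n <- nrow(X); g <- length(lev)
  means <- t(vapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]),
                    numeric(ncol(X))))
  priors <- as.vector(table(y)) / n
  Xw <- X - means[as.integer(y), , drop = FALSE]
  sv <- svd(Xw, nu = 0)
  keep <- sv$d > max(sv$d[1], 1e-12) * 1e-10
  if (!any(keep)) {
    # degenerate: no within-class variation anywhere; classify by nearest mean
    return(list(type = "nearest_mean", means = means, priors = priors,
                levels = lev))
  }
  V <- sv$v[, keep, drop = FALSE]
  s <- sv$d[keep] / sqrt(max(n - g, 1L))
  list(type = "lda", V = V, s = s, means = means, priors = priors,
       levels = lev, grand = colMeans(X))
}

lda_posterior <- function(model, X) {
  if (model$type == "nearest_mean") {
    d2 <- vapply(seq_len(nrow(model$means)), function(k)
      rowSums(sweep(X, 2L, model$means[k, ])^2), numeric(nrow(X)))
    score <- -d2 / 2 + matrix(log(model$priors), nrow(X),
                              length(model$priors), byrow = TRUE)
  } else {
    Zx <- sweep(X, 2L, model$grand) %*% model$V
    Zx <- sweep(Zx, 2L, model$s, "/")
    Zm <- sweep(model$means, 2L, model$grand) %*% model$V
    Zm <- sweep(Zm, 2L, model$s, "/")
    score <- Zx %*% t(Zm)
    score <- sweep(score, 2L, rowSums(Zm^2) / 2)
    score <- sweep(score, 2L, log(model$priors), "+")
  }
  score <- score - apply(score, 1L, max)
  P <- exp(score)
  P / rowSums(P)
}

#' Predict from a fitted classifier
#'
#' @param object an `"hc_classifier"` from [fit_classifier()].
#' @param newdata matrix with the fit-time feature width.
#' @param type `"class"` (default) or `"prob"` (posterior matrix; available
#'   for the discriminant-based kinds).
#' @param ... unused.
#' @return factor of predicted labels, or a posterior probability matrix.
#' @export
predict.hc_classifier <- function(object, newdata, type = c("class", "prob"),
                                  ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_matrix")) unclass(newdata)
       else as.matrix(newdata)
  if (ncol(X) != object$dim) {
    stop(sprintf("feature width %d does not match fit-time width %d",
                 ncol(X), object$dim), call. = FALSE)
  }
  spec <- object$spec
  if (spec$kind %in% c("svm_linear", "svm_cubic")) {
    if (type == "prob") {
      stop("posterior probabilities are not exposed for the SVM kinds",
           call. = FALSE)
    }
    m <- object$model
    Z <- sweep(sweep(X, 2L, m$center), 2L, m$scale, "/")
    return(factor(as.character(predict(m$svm, Z)), levels = object$levels))
  }
  if (spec$kind == "knn1") {
    if (type == "prob") stop("1-NN has no posterior", call. = FALSE)
    tr <- object$model$x
    # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
    d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
    nn <- apply(d2, 1L, which.min)  # first minimum = lowest training index
    return(factor(as.character(object$model$y[nn]), levels = object$levels))
  }
  P <- if (spec$kind == "lda") {
    lda_posterior(object$model, X)
  } else {
    Ps <- lapply(seq_along(object$model$learners), function(i)
      lda_posterior(object$model$learners[[i]],
                    X[, object$model$subsets[[i]], drop = FALSE]))
    Reduce(`+`, Ps) / length(Ps)
  }
  colnames(P) <- object$levels
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.hc_classifier <- function(x, ...) {
  cat(sprintf("<hc_classifier> %s, %d features, classes: %s\n",
              x$spec$kind, x$dim, paste(x$levels, collapse = ", ")))
  invisible(x)
}
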