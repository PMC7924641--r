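#' Feature matrix with provenance
#'
#' A thin wrapper around a numeric `n x d` matrix recording where the
#' features came from: provenance `"spatial"` (global-average-pooling
#' embeddings), `"stf"` (wavelet detail coefficients of those embeddings),
#' `"fused"` (concatenation across backbones) or `"reduced"`, plus the
#' source backbone name where a single backbone applies. Row names carry the
#' sample identifiers.
#'
#' @param x numeric matrix, rows = samples.
#' @param provenance one of `"spatial"`, `"stf"`, `"fused"`, `"reduced"`.
#' @param backbone source backbone name or `NA` when mixed.
#' @param sample_ids character vector of row identifiers.
#' @return object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(x, provenance, backbone = NA_character_,
                           sample_ids = rownames(x)) {
  x <- as.matrix(x)
  provenance <- match.arg(provenance, c("spatial", "stf", "fused", "reduced"))
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample_%04d", seq_len(nrow(x)))
  }
  stopifnot(length(sample_ids) == nrow(x))
  rownames(x) <- sample_ids
  structure(x, provenance = provenance, backbone = backbone,
            class = c("feature_matrix", class(x)))
}

as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) return(x)
  stop("expected a feature_matrix", call. = FALSE)
}

# row subset that keeps provenance metadata
fm_rows <- function(x, idx) {
  feature_matrix(unclass(x)[idx, , drop = FALSE],
                 provenance = attr(x, "provenance"),
                 backbone = attr(x, "backbone"),
                 sample_ids = rownames(x)[idx])
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d, provenance = %s%s\n",
              nrow(x), ncol(x), attr(x, "provenance"),
              if (is.na(attr(x, "backbone"))) ""
              else paste0(", backbone = ", attr(x, "backbone"))))
  invisible(x)
}

#' Labeled image set
#'
#' The unit flowing through preprocessing: a list of `H x W x 3` 8-bit RGB
#' arrays (stored as integer arrays with values 0..255), integer class
#' labels indexing `class_names`, a level tag, stable sample identifiers,
#' and a parent pointer per image (`NA` for originals, the source sample id
#' for augmented copies) used by the leakage audit.
#'
#' @param images list of `H x W x 3` integer arrays with values in 0..255.
#' @param labels integer vector indexing into `class_names`.
#' @param class_names ordered character vector of class names.
#' @param level `"binary"` or `"multiclass"`.
#' @param sample_ids character identifiers, unique.
#' @param parents character vector of source sample ids (`NA` = original).
#' @return object of class `"image_set"`.
#' @export
image_set <- function(images, labels, class_names,
                      level = c("multiclass", "binary"),
                      sample_ids = NULL, parents = NULL) {
  level <- match.arg(level)
  labels <- as.integer(labels)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("img_%04d", seq_along(images))
  }
  if (is.null(parents)) parents <- rep(NA_character_, length(images))
  if (length(images) != length(labels) || length(images) != length(sample_ids)) {
    stop("images, labels and sample_ids must have equal length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (length(labels) && (min(labels) < 1L || max(labels) > length(class_names))) {
    stop("labels must index into class_names", call. = FALSE)
  }
  if (level == "binary" && !identical(class_names, c("normal", "abnormal"))) {
    stop("binary level requires class_names c('normal', 'abnormal')",
         call. = FALSE)
  }
  structure(
    list(images = images, labels = labels, class_names = class_names,
         level = level, sample_ids = sample_ids, parents = parents),
    class = "image_set"
  )
}

#' @export
print.image_set <- function(x, ...) {
  counts <- table(factor(x$class_names[x$labels], levels = x$class_names))
  dims <- if (length(x$images)) paste(dim(x$images[[1]])[1:2], collapse = "x")
          else "none"
  cat(sprintf("<image_set> %d images (%s), level = %s\n",
              length(x$images), dims, x$level))
  print(counts)
  invisible(x)
}

#' @export
length.image_set <- function(x) length(x$images)

#' Subset an image set by index, keeping labels and lineage
#'
#' @param x an [image_set()].
#' @param idx integer indices of the images to keep.
#' @return an [image_set()] with the selected images.
#' @export
subset_image_set <- function(x, idx) {
  image_set(x$images[idx], x$labels[idx], x$class_names, x$level,
            x$sample_ids[idx], x$parents[idx])
}
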