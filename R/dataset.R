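#' Load a folder-per-class image dataset
#'
#' Reads a directory tree with one subfolder per class, each holding JPEG,
#' PNG or TIFF images, and returns an [image_set()]. Class names are the
#' subfolder names sorted lexicographically (C locale) for determinism;
#' sample identifiers derive from the relative file paths. Unreadable files
#' are skipped with a warning; an empty class folder (or one whose images
#' are all unreadable) is an error naming the folder.
#'
#' @param root dataset root directory.
#' @param level `"multiclass"` (default) or `"binary"`; binary trees must
#'   use the class folders `normal` and `abnormal`.
#' @return an [image_set()].
#' @export
load_image_folder <- function(root, level = c("multiclass", "binary")) {
  level <- match.arg(level)
  if (!dir.exists(root)) stop("dataset root not found: ", root, call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  dirs <- sort(dirs, method = "radix")
  if (length(dirs) < 2L) stop("need at least two class folders", call. = FALSE)
  images <- list(); labels <- integer(); ids <- character()
  for (k in seq_along(dirs)) {
    files <- sort(list.files(file.path(root, dirs[k]),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE), method = "radix")
    if (length(files) == 0L) {
      stop("class folder is empty: ", file.path(root, dirs[k]), call. = FALSE)
    }
    loaded <- 0L
    for (f in files) {
      img <- tryCatch(read_rgb_image(file.path(root, dirs[k], f)),
                      error = function(e) NULL)
      if (is.null(img)) {
        warning("skipping unreadable image: ", file.path(dirs[k], f),
                call. = FALSE)
        next
      }
      loaded <- loaded + 1L
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k)
      ids <- c(ids, paste0(dirs[k], "/", sub("\\.[^.]+$", "", f)))
    }
    if (loaded == 0L) {
      stop("no readable image in class folder: ", file.path(root, dirs[k]),
           call. = FALSE)
    }
  }
  image_set(images, labels, dirs, level = level, sample_ids = ids)
}

# decode any supported raster file to an H x W x 3 integer array in 0..255
read_rgb_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a <- aperm(a, c(2, 1, 3))  # EBImage stores x (column) first
  out <- round(pmin(pmax(a * 255, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Resize every image in a set
#'
#' Bilinear resize to a target `c(height, width)`. Images already at the
#' target size pass through pixel-identical. Labels, identifiers and
#' lineage are unchanged.
#'
#' @param data an [image_set()].
#' @param size target `c(height, width)`, default `c(224, 224)` to fit the
#'   backbone input layer.
#' @return an [image_set()] whose images all have shape `size x 3`.
#' @export
resize_images <- function(data, size = c(224L, 224L)) {
  stopifnot(inherits(data, "image_set"))
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) {
    stop("size must be two positive integers", call. = FALSE)
  }
  images <- lapply(data$images, function(img) {
    if (identical(dim(img)[1:2], size)) return(img)
    eb <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
    rs <- EBImage::resize(eb, w = size[2], h = size[1], filter = "bilinear")
    out <- round(pmin(pmax(aperm(EBImage::imageData(rs), c(2, 1, 3)) * 255,
                           0), 255))
    storage.mode(out) <- "integer"
    out
  })
  image_set(images, data$labels, data$class_names, data$level,
            data$sample_ids, data$parents)
}

#' Build the balanced binary (normal vs abnormal) level
#'
#' Keeps all `normal` images and samples `n_abnormal` tumor images without
#' replacement from the pooled remaining classes, then relabels to
#' `normal` / `abnormal`. By default the tumor draw is stratified
#' proportionally across the tumor subtypes (largest-remainder allocation);
#' `stratified = FALSE` samples uniformly from the pooled tumor images.
#'
#' @param data a multiclass [image_set()] containing a class named
#'   `"normal"`.
#' @param n_abnormal number of tumor images to keep; choosing the normal
#'   count yields an exactly balanced two-class set.
#' @param seed integer seed for the sampling.
#' @param stratified stratify the tumor draw across subtypes.
#' @return a binary-level [image_set()].
#' @export
make_binary_level <- function(data, n_abnormal, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(data, "image_set"))
  if (data$level != "multiclass" || !("normal" %in% data$class_names)) {
    stop("expected a multiclass set with a class named 'normal'", call. = FALSE)
  }
  normal_k <- match("normal", data$class_names)
  tumor_idx <- which(data$labels != normal_k)
  if (length(tumor_idx) < n_abnormal) {
    stop(sprintf("only %d tumor images available, %d requested",
                 length(tumor_idx), n_abnormal), call. = FALSE)
  }
  sel <- withr::with_seed(seed, {
    if (stratified) {
      by_class <- split(tumor_idx, data$labels[tumor_idx])
      sizes <- lengths(by_class)
      quota <- largest_remainder(n_abnormal * sizes / sum(sizes))
      unlist(Map(function(idx, q) sort(sample(idx, q)), by_class, quota),
             use.names = FALSE)
    } else {
      sort(sample(tumor_idx, n_abnormal))
    }
  })
  keep <- c(which(data$labels == normal_k), sel)
  new_labels <- ifelse(data$labels[keep] == normal_k, 1L, 2L)
  image_set(data$images[keep], new_labels, c("normal", "abnormal"),
            level = "binary", sample_ids = data$sample_ids[keep],
            parents = data$parents[keep])
}

# integer allocation by largest remainder; ties favour earlier entries
largest_remainder <- function(target) {
  base <- floor(target)
  short <- round(sum(target)) - sum(base)
  if (short > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Augmentation policy
#'
#' Random geometric augmentation: horizontal/vertical flips, pixel
#' translation, isotropic scaling, and shearing in both axes, each drawn
#' independently per generated copy. Defaults follow the study recipe:
#' translation range (-30, 30) px, scale (0.9, 1.1), shear (0, 45) degrees,
#' flips in both directions; three copies per image.
#'
#' @param flip_x,flip_y allow mirroring about the vertical / horizontal axis.
#' @param translation_px ordered integer range of the translation draw.
#' @param scale ordered range of the isotropic scale factor.
#' @param shear_deg ordered range (degrees) of the shear draw, applied
#'   independently in x and y.
#' @param per_image_copies generated copies per source image (>= 1).
#' @param seed integer seed.
#' @return object of class `"augmentation_policy"`.
#' @export
augmentation_policy <- function(flip_x = TRUE, flip_y = TRUE,
                                translation_px = c(-30L, 30L),
                                scale = c(0.9, 1.1),
                                shear_deg = c(0, 45),
                                per_image_copies = 3L, seed = 1L) {
  check_range <- function(r, what) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop(what, " must be an ordered range c(lo, hi)", call. = FALSE)
    }
  }
  check_range(translation_px, "translation_px")
  check_range(scale, "scale")
  check_range(shear_deg, "shear_deg")
  per_image_copies <- as.integer(per_image_copies)
  if (per_image_copies < 1L) stop("per_image_copies must be >= 1", call. = FALSE)
  structure(
    list(flip_x = isTRUE(flip_x), flip_y = isTRUE(flip_y),
         translation_px = translation_px, scale = scale,
         shear_deg = shear_deg, per_image_copies = per_image_copies,
         seed = as.integer(seed)),
    class = "augmentation_policy"
  )
}

#' Augment a labeled image set
#'
#' Returns the originals followed by `per_image_copies` transformed copies
#' per image. Each copy draws flip indicators, translation, scale and shear
#' from the policy's seeded stream and applies them as one composed affine
#' map (flip, then scale, then shear, then translate) about the image
#' centre, with bilinear interpolation and edge-replication fill. Copies
#' inherit the source label and record the source sample id as their
#' parent, which the cross-validation leakage audit uses.
#'
#' @param data an [image_set()] (already resized to the working size).
#' @param policy an [augmentation_policy()].
#' @return an [image_set()] with `(1 + per_image_copies) * n` images.
#' @export
augment_images <- function(data, policy) {
  stopifnot(inherits(data, "image_set"), inherits(policy, "augmentation_policy"))
  n <- length(data$images)
  images <- data$images; labels <- data$labels
  ids <- data$sample_ids; parents <- data$parents
  withr::with_seed(policy$seed, {
    for (i in seq_len(n)) {
      for (k in seq_len(policy$per_image_copies)) {
        fx <- policy$flip_x && stats::runif(1) < 0.5
        fy <- policy$flip_y && stats::runif(1) < 0.5
        tx <- stats::runif(1, policy$translation_px[1], policy$translation_px[2])
        ty <- stats::runif(1, policy$translation_px[1], policy$translation_px[2])
        sc <- stats::runif(1, policy$scale[1], policy$scale[2])
        shx <- stats::runif(1, policy$shear_deg[1], policy$shear_deg[2])
        shy <- stats::runif(1, policy$shear_deg[1], policy$shear_deg[2])
        img <- transform_image(data$images[[i]], flip_x = fx, flip_y = fy,
                               scale = sc, shear_deg = c(shx, shy),
                               translate_px = c(tx, ty))
        images[[length(images) + 1L]] <- img
        labels <- c(labels, data$labels[i])
        ids <- c(ids, sprintf("%s#aug%d", data$sample_ids[i], k))
        parents <- c(parents, data$sample_ids[i])
      }
    }
  })
  image_set(images, labels, data$class_names, data$level, ids, parents)
}

#' Apply one geometric transform to an image
#'
#' Composes flip, isotropic scale, shear and translation (in that order)
#' about the image centre and resamples with bilinear interpolation;
#' out-of-frame samples replicate the nearest edge pixel. The identity
#' parameters reproduce the input exactly, and a flip applied twice is the
#' identity.
#'
#' @param img `H x W x 3` integer array, values 0..255.
#' @param flip_x mirror left-right (about the vertical axis).
#' @param flip_y mirror top-bottom.
#' @param scale isotropic scale factor.
#' @param shear_deg `c(shear_x, shear_y)` in degrees.
#' @param translate_px `c(tx, ty)` translation in pixels (columns, rows).
#' @return transformed `H x W x 3` integer array.
#' @export
transform_image <- function(img, flip_x = FALSE, flip_y = FALSE, scale = 1,
                            shear_deg = c(0, 0), translate_px = c(0, 0)) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  # forward map (centred coords, x = column, y = row):
  #   out = Shear %*% (scale * Flip %*% src) + t
  Fm <- diag(c(if (flip_x) -1 else 1, if (flip_y) -1 else 1))
  Sh <- matrix(c(1, tanpi(shear_deg[2] / 180),
                 tanpi(shear_deg[1] / 180), 1), 2, 2)
  A <- Sh %*% (scale * Fm)
  Ainv <- solve(A)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  outx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx - translate_px[1]
  outy <- matrix(seq_len(H), H, W) - cy - translate_px[2]
  srcx <- Ainv[1, 1] * outx + Ainv[1, 2] * outy + cx
  srcy <- Ainv[2, 1] * outx + Ainv[2, 2] * outy + cy
  # clamp-to-edge bilinear sampling
  srcx <- pmin(pmax(srcx, 1), W)
  srcy <- pmin(pmax(srcy, 1), H)
  x0 <- pmin(floor(srcx), W - 1L); y0 <- pmin(floor(srcy), H - 1L)
  wx <- srcx - x0; wy <- srcy - y0
  out <- array(0L, dim = d)
  for (ch in seq_len(d[3])) {
    plane <- img[, , ch]
    i00 <- plane[cbind(c(y0), c(x0))]
    i01 <- plane[cbind(c(y0), c(x0 + 1L))]
    i10 <- plane[cbind(c(y0 + 1L), c(x0))]
    i11 <- plane[cbind(c(y0 + 1L), c(x0 + 1L))]
    v <- (1 - c(wy)) * ((1 - c(wx)) * i00 + c(wx) * i01) +
      c(wy) * ((1 - c(wx)) * i10 + c(wx) * i11)
    out[, , ch] <- as.integer(round(matrix(v, H, W)))
  }
  out
}
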