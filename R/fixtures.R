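#' Specification for a synthetic texture fixture
#'
#' Describes a deterministic five-class image set that stands in for a
#' microscopy dataset so the whole cascade can be exercised offline. Each
#' class gets a distinct texture program: `normal` is a smooth field,
#' `classic` a field of dark blobs (nucleus-like), `desmoplastic` oriented
#' stripes, `large_cell` a checkerboard, and `nodular` a few large bright
#' nodules.
#' The programs are mean-matched, so classes separate through second-order
#' (texture) statistics rather than mean intensity.
#'
#' @param n_per_class images per class; default 20, comparable to the
#'   per-class counts of a small histopathology study.
#' @param image_size `c(height, width)` in pixels.
#' @param classes ordered, duplicate-free class names; 5 classes.
#' @param seed integer; all randomness flows from this single seed.
#' @param signal_strength texture contrast in (0, 1].
#' @param noise_sd pixel noise standard deviation in 8-bit counts.
#' @return object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_per_class = 20L, image_size = c(224L, 224L),
                         classes = c("normal", "classic", "desmoplastic",
                                     "large_cell", "nodular"),
                         seed = 1L, signal_strength = 0.7, noise_sd = 8) {
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  if (is.na(n_per_class) || n_per_class < 1L) {
    stop("n_per_class must be a positive integer", call. = FALSE)
  }
  if (length(image_size) != 2L || any(image_size < 8L)) {
    stop("image_size must be two integers >= 8", call. = FALSE)
  }
  if (anyDuplicated(classes)) stop("classes must be duplicate-free", call. = FALSE)
  if (!(signal_strength > 0 && signal_strength <= 1)) {
    stop("signal_strength must lie in (0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(n_per_class = n_per_class, image_size = image_size,
         classes = classes, seed = as.integer(seed),
         signal_strength = signal_strength, noise_sd = noise_sd),
    class = "fixture_spec"
  )
}

#' Generate a deterministic synthetic texture image set
#'
#' Renders `n_per_class` RGB images per class under the texture programs of
#' [fixture_spec()], perturbed by seeded Gaussian pixel noise and seeded
#' per-image parameter jitter (stripe orientation and phase, blob
#' placement, ring centre, checker offset). Identical specs produce
#' bit-identical output; changing only the seed changes pixels but never
#' label counts.
#'
#' @param spec a [fixture_spec()].
#' @return an [image_set()] at the multiclass level with balanced classes.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  amp <- spec$signal_strength * 60
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  images <- vector("list", spec$n_per_class * length(spec$classes))
  labels <- integer(length(images))
  ids <- character(length(images))
  withr::with_seed(spec$seed, {
    i <- 0L
    for (k in seq_along(spec$classes)) {
      for (j in seq_len(spec$n_per_class)) {
        i <- i + 1L
        pattern <- switch(
          spec$classes[k],
          normal = texture_flat(rr, cc, amp),
          classic = texture_blobs(rr, cc, amp),
          desmoplastic = texture_stripes(rr, cc, amp),
          large_cell = texture_checker(rr, cc, amp),
          nodular = texture_nodules(rr, cc, amp),
          # extra class names beyond the canonical five cycle the programs
          texture_stripes(rr, cc, amp)
        )
        img <- array(0, dim = c(H, W, 3L))
        gains <- c(1.05, 1, 0.95)  # mild, class-independent channel tint
        for (ch in 1:3) {
          plane <- 127 + gains[ch] * pattern +
            matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
          img[, , ch] <- plane
        }
        storage.mode(img) <- "double"
        img <- round(pmin(pmax(img, 0), 255))
        storage.mode(img) <- "integer"
        images[[i]] <- img
        labels[i] <- k
        ids[i] <- sprintf("%s_%03d", spec$classes[k], j)
      }
    }
  })
  image_set(images, labels, spec$classes, level = "multiclass",
            sample_ids = ids)
}

# Texture programs. Each returns a zero-mean H x W pattern of amplitude
# ~amp; per-image jitter draws come from the caller's seeded RNG stream.

texture_flat <- function(rr, cc, amp) {
  # smooth low-contrast field: gentle random-phase gradient at 15% amplitude
  H <- nrow(rr); W <- ncol(rr)
  th <- stats::runif(1, 0, 2 * pi)
  g <- cos(th) * (rr - (H + 1) / 2) / H + sin(th) * (cc - (W + 1) / 2) / W
  p <- 0.15 * amp * sin(2 * pi * g + stats::runif(1, 0, 2 * pi))
  p - mean(p)
}

texture_blobs <- function(rr, cc, amp) {
  H <- nrow(rr); W <- ncol(rr)
  n_blob <- max(4L, round(0.003 * H * W / 1.5))
  p <- matrix(0, H, W)
  cy <- stats::runif(n_blob, 1, H)
  cx <- stats::runif(n_blob, 1, W)
  rad <- stats::runif(n_blob, 0.02 * H, 0.04 * H)
  for (b in seq_len(n_blob)) {
    y0 <- max(1L, floor(cy[b] - 3 * rad[b])); y1 <- min(H, ceiling(cy[b] + 3 * rad[b]))
    x0 <- max(1L, floor(cx[b] - 3 * rad[b])); x1 <- min(W, ceiling(cx[b] + 3 * rad[b]))
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - cy[b])^2, (xs - cx[b])^2, "+")
    p[ys, xs] <- p[ys, xs] - amp * exp(-d2 / (2 * rad[b]^2))
  }
  p - mean(p)
}

texture_stripes <- function(rr, cc, amp) {
  H <- nrow(rr)
  period <- stats::runif(1, 0.09, 0.13) * H
  th <- stats::runif(1, 0, pi)
  phase <- stats::runif(1, 0, 2 * pi)
  p <- amp * sin(2 * pi * (cos(th) * rr + sin(th) * cc) / period + phase)
  p - mean(p)
}

texture_checker <- function(rr, cc, amp) {
  H <- nrow(rr)
  scale <- stats::runif(1, 0.1, 0.15) * H
  oy <- stats::runif(1, 0, scale); ox <- stats::runif(1, 0, scale)
  p <- amp * sign(sin(pi * (rr + oy) / scale)) * sign(sin(pi * (cc + ox) / scale))
  p - mean(p)
}

texture_nodules <- function(rr, cc, amp) {
  # few large bright nodules: opposite polarity and ~3x the scale of the
  # blob program, so the two differ in spatially-averaged statistics
  H <- nrow(rr); W <- ncol(rr)
  n_nod <- max(2L, round(6 * H * W / 224^2))
  p <- matrix(0, H, W)
  cy <- stats::runif(n_nod, 1, H)
  cx <- stats::runif(n_nod, 1, W)
  rad <- stats::runif(n_nod, 0.07 * H, 0.11 * H)
  for (b in seq_len(n_nod)) {
    y0 <- max(1L, floor(cy[b] - 3 * rad[b])); y1 <- min(H, ceiling(cy[b] + 3 * rad[b]))
    x0 <- max(1L, floor(cx[b] - 3 * rad[b])); x1 <- min(W, ceiling(cx[b] + 3 * rad[b]))
    ys <- y0:y1; xs <- x0:x1
    d2 <- outer((ys - cy[b])^2, (xs - cx[b])^2, "+")
    p[ys, xs] <- p[ys, xs] + amp * exp(-d2 / (2 * rad[b]^2))
  }
  p - mean(p)
}

#' Write a fixture as a folder-per-class PNG tree
#'
#' Dumps an [image_set()] to `dir/<class>/<sample_id>.png`, the layout
#' expected by [load_image_folder()].
#'
#' @param set an [image_set()].
#' @param dir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(set, dir, force = FALSE) {
  stopifnot(inherits(set, "image_set"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory exists and is non-empty; use force = TRUE",
         call. = FALSE)
  }
  for (k in seq_along(set$class_names)) {
    dir.create(file.path(dir, set$class_names[k]), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (i in seq_along(set$images)) {
    cls <- set$class_names[set$labels[i]]
    png::writePNG(set$images[[i]] / 255,
                  file.path(dir, cls, paste0(set$sample_ids[i], ".png")))
  }
  invisible(dir)
}
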