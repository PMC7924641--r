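#' Backbone specification
#'
#' Names one of the three convolutional feature extractors and fixes its
#' contractual global-average-pooling (GAP) width: 2048 for `resnet50`,
#' 1920 for `densenet201`, 1280 for `mobilenet`. The head is a
#' `num_classes`-way softmax layer replacing the original 1000-class layer.
#'
#' The package builds each backbone as a compact convolutional network in
#' the architectural style of its namesake (residual bottleneck /
#' densely-connected blocks / depthwise-separable convolutions) with
#' seeded He-initialised weights. No pretrained ImageNet weights ship with
#' the package, so `pretrained = TRUE` is only usable against a local
#' weight cache; without one, building errors with a pointer to
#' `pretrained = FALSE`. Every dimension contract holds regardless of the
#' weights.
#'
#' @param name `"resnet50"`, `"densenet201"` or `"mobilenet"`.
#' @param pretrained request cached pretrained weights (see Details).
#' @param num_classes 2 (binary level) or 4 (subtype level).
#' @return object of class `"backbone_spec"` with a `feature_dim` field.
#' @export
backbone_spec <- function(name = c("resnet50", "densenet201", "mobilenet"),
                          pretrained = FALSE, num_classes = 2L) {
  name <- match.arg(name)
  num_classes <- as.integer(num_classes)
  if (!num_classes %in% c(2L, 4L)) {
    stop("num_classes must be 2 or 4", call. = FALSE)
  }
  dims <- c(resnet50 = 2048L, densenet201 = 1920L, mobilenet = 1280L)
  structure(
    list(name = name, pretrained = isTRUE(pretrained),
         num_classes = num_classes, feature_dim = dims[[name]]),
    class = "backbone_spec"
  )
}

#' Build a backbone feature extractor
#'
#' Instantiates the architecture named by the spec with its final
#' fully-connected head replaced by a `num_classes`-way softmax layer.
#' Weights are He-initialised from the given seed; the forward pass is
#' deterministic (inference mode, no stochastic layers).
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for the weight draw.
#' @return object of class `"backbone"`.
#' @export
build_backbone <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$pretrained) {
    stop("no pretrained weight cache is available; ",
         "use backbone_spec(..., pretrained = FALSE) for seeded random ",
         "initialisation (all dimension contracts hold regardless of weights)",
         call. = FALSE)
  }
  layers <- withr::with_seed(seed, backbone_layers(spec$name))
  head <- withr::with_seed(seed + 1L, list(
    W = matrix(stats::rnorm(spec$feature_dim * spec$num_classes,
                            sd = 1 / sqrt(spec$feature_dim)),
               spec$feature_dim, spec$num_classes),
    b = numeric(spec$num_classes),
    center = NULL, scale = NULL  # set by fine_tune
  ))
  structure(
    list(spec = spec, layers = layers, head = head, seed = as.integer(seed),
         loss_history = numeric(0)),
    class = "backbone"
  )
}

# ---- architectures ---------------------------------------------------------
# Compact networks keeping each namesake's structural signature and final
# channel count. Layer descriptors are interpreted by forward_backbone().

he_w <- function(k, cin, cout) {
  matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

conv_layer <- function(k, stride, cin, cout, pad = k %/% 2L) {
  list(type = "conv", k = k, stride = stride, pad = pad,
       W = he_w(k, cin, cout), b = numeric(cout), cin = cin, cout = cout)
}

dw_layer <- function(stride, cin) {
  list(type = "dwconv", k = 3L, stride = stride, pad = 1L,
       W = array(stats::rnorm(9L * cin, sd = sqrt(2 / 9)), c(3L, 3L, cin)),
       cin = cin, cout = cin)
}

backbone_layers <- function(name) {
  switch(
    name,
    resnet50 = list(
      conv_layer(7L, 4L, 3L, 32L, pad = 3L), list(type = "relu"),
      list(type = "maxpool"),
      list(type = "residual",
           main = list(conv_layer(3L, 2L, 32L, 64L), list(type = "relu"),
                       conv_layer(3L, 1L, 64L, 64L)),
           shortcut = list(conv_layer(1L, 2L, 32L, 64L, pad = 0L))),
      list(type = "relu"),
      conv_layer(3L, 2L, 64L, 128L), list(type = "relu"),
      conv_layer(1L, 1L, 128L, 2048L, pad = 0L), list(type = "relu")
    ),
    densenet201 = list(
      conv_layer(7L, 4L, 3L, 32L, pad = 3L), list(type = "relu"),
      list(type = "maxpool"),
      list(type = "dense_block",
           convs = list(conv_layer(3L, 1L, 32L, 16L),
                        conv_layer(3L, 1L, 48L, 16L),
                        conv_layer(3L, 1L, 64L, 16L))),
      conv_layer(1L, 1L, 80L, 64L, pad = 0L), list(type = "relu"),
      list(type = "avgpool"),
      list(type = "dense_block",
           convs = list(conv_layer(3L, 1L, 64L, 16L),
                        conv_layer(3L, 1L, 80L, 16L))),
      list(type = "avgpool"),
      conv_layer(1L, 1L, 96L, 1920L, pad = 0L), list(type = "relu")
    ),
    mobilenet = list(
      conv_layer(3L, 4L, 3L, 32L, pad = 1L), list(type = "relu"),
      dw_layer(2L, 32L), conv_layer(1L, 1L, 32L, 64L, pad = 0L),
      list(type = "relu"),
      dw_layer(2L, 64L), conv_layer(1L, 1L, 64L, 128L, pad = 0L),
      list(type = "relu"),
      dw_layer(2L, 128L), conv_layer(1L, 1L, 128L, 256L, pad = 0L),
      list(type = "relu"),
      conv_layer(1L, 1L, 256L, 1280L, pad = 0L), list(type = "relu")
    )
  )
}

# ---- forward pass ----------------------------------------------------------

# per-channel ImageNet normalisation of an H x W x 3 image in 0..255
normalize_input <- function(img) {
  m <- c(0.485, 0.456, 0.406); s <- c(0.229, 0.224, 0.225)
  x <- img / 255
  for (ch in 1:3) x[, , ch] <- (x[, , ch] - m[ch]) / s[ch]
  x
}

conv_forward <- function(x, layer) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  Ho <- (H + 2L * p - k) %/% s + 1L
  Wo <- (W + 2L * p - k) %/% s + 1L
  if (Ho < 1L || Wo < 1L) stop("image too small for backbone", call. = FALSE)
  xp <- array(0, dim = c(H + 2L * p, W + 2L * p, Cin))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  # im2col: rows = output pixels, cols = k*k*Cin patch entries
  oy <- rep(seq.int(1L, by = s, length.out = Ho), times = Wo)
  ox <- rep(seq.int(1L, by = s, length.out = Wo), each = Ho)
  Hp <- H + 2L * p
  base <- (ox - 1L) * Hp + oy                       # linear index of patch corner
  off <- as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+"))
  idx <- outer(base, off, "+")                       # (Ho*Wo) x (k*k)
  plane_len <- Hp * (W + 2L * p)
  P <- matrix(0, Ho * Wo, k * k * Cin)
  for (ch in seq_len(Cin)) {
    P[, (ch - 1L) * k * k + seq_len(k * k)] <- xp[idx + (ch - 1L) * plane_len]
  }
  y <- P %*% layer$W
  y <- sweep(y, 2L, layer$b, "+")
  array(y, dim = c(Ho, Wo, layer$cout))
}

# depthwise 3x3 convolution via shift-and-add, zero padding
dwconv_forward <- function(x, layer) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  s <- layer$stride
  xp <- array(0, dim = c(H + 2L, W + 2L, Cin))
  xp[1L + seq_len(H), 1L + seq_len(W), ] <- x
  Ho <- (H + 2L - 3L) %/% s + 1L
  Wo <- (W + 2L - 3L) %/% s + 1L
  ys <- seq.int(1L, by = s, length.out = Ho)
  xs <- seq.int(1L, by = s, length.out = Wo)
  out <- array(0, dim = c(Ho, Wo, Cin))
  for (dy in 0:2) for (dx in 0:2) {
    w <- layer$W[dy + 1L, dx + 1L, ]
    out <- out + sweep(xp[ys + dy, xs + dx, , drop = FALSE], 3L, w, "*")
  }
  out
}

pool2 <- function(x, fun) {
  d <- dim(x); Ho <- d[1] %/% 2L; Wo <- d[2] %/% 2L
  a <- x[seq_len(2L * Ho), seq_len(2L * Wo), , drop = FALSE]
  i1 <- seq.int(1L, by = 2L, length.out = Ho)
  i2 <- seq.int(2L, by = 2L, length.out = Ho)
  j1 <- seq.int(1L, by = 2L, length.out = Wo)
  j2 <- seq.int(2L, by = 2L, length.out = Wo)
  fun(fun(a[i1, j1, , drop = FALSE], a[i1, j2, , drop = FALSE]),
      fun(a[i2, j1, , drop = FALSE], a[i2, j2, , drop = FALSE]))
}

apply_layers <- function(x, layers) {
  for (layer in layers) {
    x <- switch(layer$type,
                conv = conv_forward(x, layer),
                dwconv = dwconv_forward(x, layer),
                relu = pmax(x, 0),
                maxpool = pool2(x, pmax),
                avgpool = pool2(x, function(a, b) (a + b) / 2),
                residual = {
                  pmax(apply_layers(x, layer$main) +
                         apply_layers(x, layer$shortcut), 0)
                },
                dense_block = {
                  for (cv in layer$convs) {
                    x <- array(c(x, pmax(conv_forward(x, cv), 0)),
                               dim = dim(x) + c(0L, 0L, cv$cout))
                  }
                  x
                },
                stop("unknown layer type: ", layer$type))
  }
  x
}

# GAP embedding of one image
forward_gap <- function(model, img) {
  act <- apply_layers(normalize_input(img), model$layers)
  colMeans(matrix(act, ncol = dim(act)[3]))
}

#' Extract global-average-pooling features
#'
#' Runs the convolutional body on every image and reads out the spatial
#' mean of each final-stage channel — the GAP embedding. Row order follows
#' the input; identical images give identical rows.
#'
#' @param model a [build_backbone()] model.
#' @param data an [image_set()].
#' @return an `n x feature_dim` [feature_matrix()] with provenance
#'   `"spatial"` and the backbone recorded.
#' @export
extract_gap_features <- function(model, data) {
  stopifnot(inherits(model, "backbone"), inherits(data, "image_set"))
  feats <- t(vapply(data$images, function(img) forward_gap(model, img),
                    numeric(model$spec$feature_dim)))
  feature_matrix(feats, provenance = "spatial",
                 backbone = model$spec$name, sample_ids = data$sample_ids)
}

#' Training configuration for backbone fine-tuning
#'
#' Defaults follow the study recipe: stochastic gradient descent with
#' momentum (SGDM), 20 epochs, initial learning rate `3e-4`, mini-batch 4,
#' momentum coefficient 0.9.
#'
#' @param epochs number of passes over the training set (0 = no-op).
#' @param initial_lr learning rate.
#' @param batch_size mini-batch size.
#' @param momentum momentum coefficient.
#' @param seed integer seed governing shuffling.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(epochs = 20L, initial_lr = 3e-4, batch_size = 4L,
                         momentum = 0.9, seed = 1L) {
  epochs <- as.integer(epochs)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (initial_lr <= 0) stop("initial_lr must be > 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(epochs = epochs, initial_lr = initial_lr,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Fine-tune a backbone's classification head
#'
#' Transfer-learning step: the convolutional body stays frozen and the
#' replaced fully-connected head is trained by mini-batch SGDM on the
#' cross-entropy loss over GAP embeddings (z-scored with training-set
#' statistics, recorded in the head). With `epochs = 0` the model is
#' returned unchanged. The mean training loss per epoch is recorded in
#' `loss_history`.
#'
#' @param model a [build_backbone()] model.
#' @param train an [image_set()]; labels must match the head width.
#' @param cfg a [train_config()].
#' @return the fine-tuned `"backbone"` model.
#' @export
fine_tune <- function(model, train, cfg = train_config()) {
  stopifnot(inherits(model, "backbone"), inherits(train, "image_set"),
            inherits(cfg, "train_config"))
  if (length(unique(train$labels)) > model$spec$num_classes ||
      max(train$labels) > model$spec$num_classes) {
    stop("training labels exceed the head's num_classes", call. = FALSE)
  }
  if (cfg$epochs == 0L) return(model)
  X <- unclass(extract_gap_features(model, train))
  y <- train$labels
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  n <- nrow(Z); K <- model$spec$num_classes
  W <- model$head$W; b <- model$head$b
  vW <- W * 0; vb <- b * 0
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  losses <- numeric(cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq.int(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Zi <- Z[idx, , drop = FALSE]
        logits <- sweep(Zi %*% W, 2L, b, "+")
        logits <- logits - apply(logits, 1L, max)
        P <- exp(logits); P <- P / rowSums(P)
        ep_loss <- ep_loss - sum(log(P[cbind(seq_along(idx), y[idx])] + 1e-300))
        G <- (P - Y[idx, , drop = FALSE]) / length(idx)
        gW <- crossprod(Zi, G); gb <- colSums(G)
        vW <- cfg$momentum * vW - cfg$initial_lr * gW
        vb <- cfg$momentum * vb - cfg$initial_lr * gb
        W <- W + vW; b <- b + vb
      }
      losses[ep] <- ep_loss / n
    }
  })
  model$head$W <- W; model$head$b <- b
  model$head$center <- ctr; model$head$scale <- scl
  model$loss_history <- c(model$loss_history, losses)
  model
}

#' End-to-end class prediction
#'
#' Forward pass through the convolutional body, the (optionally fine-tuned)
#' softmax head, and an arg-max over classes.
#'
#' @param model a [build_backbone()] model, usually after [fine_tune()].
#' @param data an [image_set()].
#' @param type `"class"` for label indices, `"prob"` for the softmax matrix.
#' @return integer labels in `1..num_classes`, or an `n x num_classes`
#'   probability matrix.
#' @export
predict_end_to_end <- function(model, data, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- unclass(extract_gap_features(model, data))
  if (!is.null(model$head$center)) {
    X <- sweep(sweep(X, 2L, model$head$center), 2L, model$head$scale, "/")
  }
  logits <- sweep(X %*% model$head$W, 2L, model$head$b, "+")
  logits <- logits - apply(logits, 1L, max)
  P <- exp(logits); P <- P / rowSums(P)
  if (type == "prob") P else max.col(P, ties.method = "first")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone> %s, GAP width %d, head %d classes%s\n",
              x$spec$name, x$spec$feature_dim, x$spec$num_classes,
              if (length(x$loss_history)) " (fine-tuned)" else ""))
  invisible(x)
}
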