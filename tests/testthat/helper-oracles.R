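# Independent oracles used across tests. These deliberately use naive
# formulations (explicit loops, O(N^2) sums, dense eigensolves) so they stay
# independent of the package's implementation paths.

# naive single-level decimated filtering: explicit half-point symmetric
# extension, explicit convolution loop, explicit downsampling
oracle_dwt <- function(x, taps) {
  N <- length(x); L <- length(taps)
  reflect <- function(p) {
    q <- (p - 1) %% (2 * N)
    if (q < N) q + 1 else 2 * N - q
  }
  ext <- vapply(seq(-(L - 2), N + L - 1), function(p) x[reflect(p)], numeric(1))
  full <- numeric(length(ext) + L - 1)
  for (k in seq_along(full)) {
    acc <- 0
    for (j in seq_len(L)) {
      i <- k - j + 1
      if (i >= 1 && i <= length(ext)) acc <- acc + taps[j] * ext[i]
    }
    full[k] <- acc
  }
  full[seq(L + 1, by = 2, length.out = (N + L - 1) %/% 2)]
}

# naive orthonormal DCT-II of one vector by direct cosine summation
oracle_dct <- function(x) {
  N <- length(x)
  out <- numeric(N)
  for (k in 0:(N - 1)) {
    s <- 0
    for (j in 0:(N - 1)) s <- s + x[j + 1] * cos(pi * (j + 0.5) * k / N)
    out[k + 1] <- s * sqrt(2 / N) * (if (k == 0) 1 / sqrt(2) else 1)
  }
  out
}

# shared small fixture and derived features, computed once per test run
.cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.cache$set)) {
    .cache$set <- generate_fixture(
      fixture_spec(n_per_class = 10L, image_size = c(96L, 96L), seed = 11L))
  }
  .cache$set
}

fuse_set <- function(set, seed0 = 20L) {
  models <- lapply(seq_along(c("resnet50", "densenet201", "mobilenet")),
                   function(b) build_backbone(
                     backbone_spec(c("resnet50", "densenet201",
                                     "mobilenet")[b]), seed = seed0 + b))
  stf <- lapply(models, function(m)
    stf_transform(extract_gap_features(m, set)))
  concat_fused(stf)
}

small_fused_features <- function() {
  if (is.null(.cache$fused)) .cache$fused <- fuse_set(small_fixture())
  .cache$fused
}

# fused features of the generator's study-scale defaults (20/class, 224 px)
study_fixture <- function() {
  if (is.null(.cache$study)) .cache$study <- generate_fixture(fixture_spec())
  .cache$study
}

study_fused_features <- function() {
  if (is.null(.cache$study_fused)) {
    .cache$study_fused <- fuse_set(study_fixture(), seed0 = 1L)
  }
  .cache$study_fused
}
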