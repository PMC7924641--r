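---
title: "Methods: the deep-wavelet fusion cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the deep-wavelet fusion cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

histocascade classifies RGB microscopy images at two levels: a binary
normal-versus-tumor screen and a four-way tumor-subtype call aimed at
pediatric medulloblastoma histopathology (classic, desmoplastic, large
cell, nodular). Studies of this kind work with very small datasets (tens
of images per class), which rules out training a deep network from
scratch. The cascade therefore composes four stages, each individually
standard, whose combination is the method:

1. **Spatial deep features.** Each 224×224×3 image is embedded by a
   convolutional backbone read out at the global-average-pooling (GAP)
   layer: the spatial mean of every final-stage channel. The three
   backbones have GAP widths 2048 (`resnet50`), 1920 (`densenet201`) and
   1280 (`mobilenet`); the widths are architectural constants,
   independent of image content and input size.
2. **Wavelet detail features.** Each embedding $x \in \mathbb{R}^N$ is
   passed through one level of a discrete wavelet transform with the
   discrete Meyer (dmey) filter, and only the detail (highpass)
   coefficients $CD_1$ are kept. With the packaged 102-tap filter and
   half-point symmetric boundary extension the output length is
   $\lfloor (N + L - 1)/2 \rfloor$, i.e. 1074, 1010 and 690 for the
   three backbones. The motivation is that diagnostically relevant
   texture lives in the high-frequency band; the transform also halves
   the dimension.
3. **Fusion and reduction.** The three detail vectors are concatenated
   (width $1074 + 1010 + 690 = 2774$) and reduced either by keeping the
   first $n$ coefficients of an orthonormal DCT-II applied per row, or by
   projecting on the top $n$ principal components fitted on training
   rows. $n$ is chosen by a sequential forward search: an increasing
   candidate grid is scored by repeated cross-validated accuracy and the
   smallest candidate achieving the maximum wins.
4. **Classification.** Five classical classifiers are supported behind
   one fit/predict contract: linear SVM, cubic SVM, 1-nearest-neighbour,
   LDA, and a random-subspace discriminant ensemble (30 learners on
   random feature subsets of size $\min(1024, d)$, posteriors averaged).

Evaluation uses stratified 5-fold cross-validation repeated 5 times, with
accuracy, sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$ and
precision $TP/(TP+FP)$; multiclass metrics are computed one-vs-rest per
class and macro-averaged, and ratios with a zero denominator are reported
as `NaN`, never silently zero.

The four scenarios of `run_scenario()` ablate the cascade: end-to-end
backbone classification (I), classical classifiers on spatial features
(II), on wavelet-detail features (III), and on the fused-and-reduced
representation (IV, the full method).

## Backbone design

No deep-learning framework is part of this package's dependency set, and
no pretrained ImageNet weights ship with it. The backbones are compact
convolutional networks written in base R (im2col matrix-multiply
convolutions) that keep each namesake's structural signature — residual
bottleneck blocks, densely-connected blocks with concatenation, and
depthwise-separable convolutions respectively — and, crucially, the
contractual GAP widths. Weights are He-initialised from a caller-supplied
seed, so extraction is a fixed, deterministic random projection of local
image texture. Random convolutional features are a well-studied baseline
and are sufficient for every dimension contract and for linearly
separable texture classes; they do not match the discriminative power of
ImageNet-pretrained weights, which is one reason the package makes no
claim about reproducing published accuracies on real histopathology
images (the other being that the real dataset is an external download).
Requesting `pretrained = TRUE` without a local weight cache errors with a
pointer to `pretrained = FALSE`.

Fine-tuning (`fine_tune()`) follows the classic transfer-learning recipe
for tiny datasets: the convolutional body stays frozen and the replaced
`num_classes`-way softmax head is trained by mini-batch SGDM
(cross-entropy, momentum 0.9, defaults 20 epochs, learning rate
$3\times10^{-4}$, batch 4) on GAP embeddings z-scored with training-set
statistics. A consequence worth stating: because the body is frozen, GAP
features are identical before and after fine-tuning, so the question of
whether scenarios II–IV should extract from fine-tuned or initial weights
dissolves — extraction is leakage-free by construction and computed once
for all folds.

## The discrete Meyer filter

The published coefficient lengths (1074/1010/690) pin the filter length
at $L = 102$ taps. The package constructs the decomposition lowpass
filter from first principles: the Meyer conjugate-mirror-filter frequency
response $H(\omega) = \sqrt2\,\hat\varphi(2\omega)$ (with the standard
degree-7 polynomial ramp) is sampled on a $2^{14}$-point grid,
inverse-DFT'd, truncated to the 102 central taps, and then
Newton-projected onto the orthogonality constraints (even-lag
autocorrelations equal to the Kronecker delta, tap sum $\sqrt2$,
alternating sum 0). Plain truncation leaves a perfect-reconstruction
defect of order $10^{-6}$; the projection reduces it to order $10^{-11}$
while moving the taps by less than $10^{-4}$, so the filter remains a
faithful Meyer approximant and the level-1 analysis/synthesis round trip
is exact to well below the package's $10^{-8}$ test tolerance. The taps
ship as a plain-text asset (`extdata/dmey102.txt`) with a checksum; a
test regenerates them from `build_dmey_taps()` and compares.

Boundary handling is fixed to half-point symmetric extension (the edge
sample is repeated), which is the convention under which the published
lengths arise; the detail branch downsamples the full convolution at
0-based indices $L, L+2, \dots$ Alternative extensions change output
lengths and are deliberately not offered.

## Numerical choices

* **DCT-II** is implemented as an explicit orthonormal cosine matrix
  (the first $n$ rows suffice for truncation); tests compare it to a
  naive $O(N^2)$ cosine-sum oracle and assert Parseval's identity.
* **PCA** uses `stats::prcomp` (SVD), centring only, no variance
  scaling; explained variances are tested against a brute-force
  covariance eigendecomposition.
* **LDA** uses a pseudo-inverse pooled covariance computed in the span
  of the within-class scatter (SVD with relative tolerance $10^{-10}$),
  so it stays defined when $d \gg n$, which happens whenever the
  2774-wide fused features are classified directly. Directions in the
  scatter's null space are ignored, the standard pseudo-inverse
  behaviour. On well-conditioned data it agrees with `MASS::lda` to
  $10^{-6}$ in posteriors (tested).
* **SVMs** delegate to `e1071::svm` with cost 1, one-vs-one multiclass,
  and features z-scored with training statistics in the wrapper (so
  constant columns are handled deterministically). The cubic kernel is
  $(x\cdot x'/d + 1)^3$. The box constraint and kernel scale are
  declared defaults, not values inferred from any publication.
* **1-NN** computes Euclidean distances by the inner-product expansion
  and breaks exact distance ties by the lowest training index
  (`which.min`); `class::knn` is the cross-check where ties cannot
  occur.
* **Ensemble** subspace draws flow from the classifier spec's seed; the
  degenerate ensemble (one learner, full subspace) provably equals plain
  LDA and is tested as such.
* **Fold assignment** shuffles each class and deals it round-robin, so
  per-fold class counts deviate from proportionality by at most one.
  Repeat $r$ seeds with `base_seed + r`, making any repeat reproducible
  alone. A class smaller than $k$ is an error naming the class.
* All stochastic steps take explicit seeds and restore the caller's RNG
  state (`withr::with_seed`); nothing reads or mutates global RNG state
  as a side effect.

## Leakage discipline

Every fitted component — fine-tuned head, PCA mean and components,
classifier, standardisation — is fitted on training-fold rows only, and
records the sample ids it saw. Augmented copies carry their source id as
a parent. `audit_leakage()` walks every fold of a report and errors if a
test id (or a copy derived from one) appears in any fitted component's
lineage; the test suite runs the audit on every scenario and also checks
that a forged lineage trips it. Because augmenting before splitting would
place near-duplicates of test images into training folds, augmentation is
applied inside folds, to training images only. Whether the original
workflow augmented before or inside cross-validation is not determinable
from the publication record; the leakage-free protocol is the default and
the only one wired into `run_scenario()`'s augmentation path.

## The synthetic fixture

`generate_fixture()` renders a five-class texture set standing in for the
histopathology data: a smooth field (`normal`), dense small dark blobs
(`classic`, nucleus-like), oriented stripes (`desmoplastic`), a
checkerboard (`large_cell`), and a few large bright nodules (`nodular`).
All programs are mean-matched, so classes separate through second-order
statistics — contrast, gradient structure, spatial correlation — not mean
intensity; per-image jitter (orientation, phase, placement, period)
makes the classes manifolds rather than points. The fifth program was
originally concentric rings, but a spatially-averaged embedding cannot
distinguish rings from orientation-jittered stripes (GAP integrates out
orientation), so the generator uses nodules instead — which is also the
more faithful emulation of extensive-nodularity histology.

Defaults were chosen once as study-scale conditions: 20 images per class
(comparable to the real per-class counts of 23–59), 224×224 px, signal
strength 0.7 (texture amplitude 42 of 255), noise sd 8 counts. What the
fixture deliberately does **not** emulate: H&E stain statistics, nuclear
morphology, slide-level artefacts, class-imbalanced long tails, or any
intra-class heterogeneity beyond parameter jitter. Passing tests
demonstrate that the pipeline's plumbing, contracts and protocol are
correct and that the cascade separates designed texture classes; they say
nothing about accuracy on real medulloblastoma slides.

On these defaults the full Scenario IV cascade (PCA, 25 components, LDA,
5-fold × 5 repeats) reaches mean cross-validated accuracy ≈ 0.996–1.0
depending on seed, which the acceptance script recomputes end-to-end.
A deliberately mean-matched consequence: a linear discriminant on raw
16×16 thumbnail pixels performs near chance (pinned at 0.26 against a
0.20 chance level), while the same discriminant on four second-order
thumbnail summaries is perfect — the separability is in the texture
statistics, by design.

## Problem sizes in the test suite

The suite exercises full-size (224 px) images where a contract demands it
(GAP widths, resize) and a 10-per-class, 96 px fixture elsewhere; the
permutation-null and end-to-end checks run at the generator's study-scale
defaults. These sizes are the package's own choice of smallest
convincing problem for each property.

## Known limitations

* Random-weight backbones: dimension contracts and protocol are exact,
  representational quality is a baseline. A weight cache can be wired in
  through `build_backbone()`'s spec, but no loader for published
  checkpoint formats is included.
* `fine_tune()` trains the head only; there is no full-network
  backpropagation.
* The dmey filter is the only packaged wavelet; `wavelet_filter()`
  accepts any orthogonal pair but multi-level decompositions are out of
  scope.
* The sequential forward search evaluates a user-supplied grid; it is a
  dimension sweep, not a wrapper-style per-feature selection.
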