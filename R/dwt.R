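#' Single-level discrete wavelet transform of a vector
#'
#' Computes level-1 approximation (CA1) and detail (CD1) coefficients under
#' half-point symmetric boundary extension: the signal is extended by
#' `L - 1` samples per side by mirroring about the boundary (the edge sample
#' is repeated), fully convolved with the decomposition filter, and
#' dyadically downsampled. Both coefficient vectors have length
#' `floor((N + L - 1) / 2)` for a length-`N` input and `L` filter taps.
#'
#' @param x numeric vector, length at least 2.
#' @param filt a [wavelet_filter()].
#' @return `dwt_level1()` returns `list(ca, cd)`; [dwt_detail_level1()]
#'   returns only the detail (highpass) coefficients.
#' @export
dwt_level1 <- function(x, filt) {
  stopifnot(inherits(filt, "wavelet_filter"))
  x <- as.numeric(x)
  if (length(x) < 2L) stop("input signal must have length >= 2", call. = FALSE)
  list(ca = decimated_filter(x, filt$lowpass_dec),
       cd = decimated_filter(x, filt$highpass_dec))
}

#' @rdname dwt_level1
#' @export
dwt_detail_level1 <- function(x, filt) {
  stopifnot(inherits(filt, "wavelet_filter"))
  x <- as.numeric(x)
  if (length(x) < 2L) stop("input signal must have length >= 2", call. = FALSE)
  decimated_filter(x, filt$highpass_dec)
}

# Half-point symmetric extension by L-1 per side, full convolution, then
# downsampling at 0-based full-convolution indices L, L+2, ... This matches
# the convention under which length-2048/1920/1280 inputs give 1074/1010/690
# detail coefficients with a 102-tap filter.
decimated_filter <- function(x, taps) {
  N <- length(x)
  L <- length(taps)
  ext <- x[fold_symmetric(seq.int(-(L - 2L), N + L - 1L), N)]
  full <- conv_full(ext, taps)
  full[seq.int(L + 1L, by = 2L, length.out = (N + L - 1L) %/% 2L)]
}

# Map arbitrary integer positions onto 1..N by half-point symmetric
# (edge-repeating) reflection, period 2N.
fold_symmetric <- function(pos, N) {
  q <- (pos - 1L) %% (2L * N)
  ifelse(q < N, q + 1L, 2L * N - q)
}

# full linear convolution; FFT-based for long inputs, direct otherwise
conv_full <- function(a, b) {
  na <- length(a); nb <- length(b)
  n <- na + nb - 1L
  if (n < 256L) {
    out <- numeric(n)
    for (j in seq_len(nb)) {
      out[j:(j + na - 1L)] <- out[j:(j + na - 1L)] + b[j] * a
    }
    out
  } else {
    m <- stats::nextn(n, 2)
    fa <- stats::fft(c(a, numeric(m - na)))
    fb <- stats::fft(c(b, numeric(m - nb)))
    Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / m
  }
}

#' Invert a single-level discrete wavelet transform
#'
#' Reconstructs the original signal from level-1 approximation and detail
#' coefficients: both branches are dyadically upsampled, convolved with the
#' time-reversed decomposition filters, summed, and trimmed. With an
#' orthogonal filter pair this reproduces the input of [dwt_level1()] to
#' within the filter's perfect-reconstruction accuracy.
#'
#' @param ca,cd level-1 approximation and detail coefficients.
#' @param filt the [wavelet_filter()] used for decomposition.
#' @param n length of the original signal.
#' @return numeric vector of length `n`.
#' @export
idwt_level1 <- function(ca, cd, filt, n) {
  stopifnot(inherits(filt, "wavelet_filter"), length(ca) == length(cd))
  L <- filt$length
  up <- function(c) {
    u <- numeric(2L * length(c))
    u[seq.int(1L, by = 2L, length.out = length(c))] <- c
    u
  }
  rec <- conv_full(up(ca), rev(filt$lowpass_dec)) +
    conv_full(up(cd), rev(filt$highpass_dec))
  rec[seq.int(L - 1L, length.out = n)]
}

#' Wavelet detail ("spatial-time-frequency") transform of a feature matrix
#'
#' Applies [dwt_detail_level1()] to every row of a spatial deep-feature
#' matrix, turning each global-average-pooling embedding into its level-1
#' discrete Meyer detail coefficients. Row order, sample identifiers and the
#' source backbone record are preserved; the provenance tag becomes `"stf"`.
#'
#' @param feats a [feature_matrix()] with provenance `"spatial"`.
#' @param filt a [wavelet_filter()]; defaults to the packaged 102-tap
#'   discrete Meyer filter.
#' @return a [feature_matrix()] with provenance `"stf"` and
#'   `floor((d + L - 1)/2)` columns for `d` input columns.
#' @export
stf_transform <- function(feats, filt = dmey_filter()) {
  x <- as_feature_matrix(feats)
  if (!identical(attr(x, "provenance"), "spatial")) {
    stop("stf_transform expects a feature matrix with provenance 'spatial'",
         call. = FALSE)
  }
  out <- t(apply(unclass(x), 1L, dwt_detail_level1, filt = filt))
  feature_matrix(out, provenance = "stf",
                 backbone = attr(x, "backbone"),
                 sample_ids = rownames(x))
}
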