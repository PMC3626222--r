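# Discrete transform conventions used throughout:
#   forward kernel exp(-j 2 pi k.r), unitary normalisation 1/sqrt(N) per plane,
#   FFT-native ordering (DC at [1,1]); fftshift2() recenters for display.

#' Spatial-frequency sample positions for an FFT-native axis
#'
#' Frequencies in cycles per micron for an axis of `n` samples at spacing
#' `d` microns, in the order `stats::fft()` uses (DC first, negative
#' frequencies in the upper half).
#'
#' @param n Number of samples.
#' @param d Sample spacing (µm).
#' @return Numeric vector of length `n` (cycles/µm).
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' @keywords internal
fft2_unitary <- function(x) stats::fft(x) / sqrt(length(x))

#' @keywords internal
ifft2_unitary <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Unnormalised inverse transform: sum_k X_k exp(+j 2 pi k.r / n).  Together
# with unitary spectra this evaluates circular cross-correlations exactly
# (see correlate_plane()).
#' @keywords internal
ifft2_raw <- function(x) stats::fft(x, inverse = TRUE)

#' @keywords internal
fftn_unitary <- function(x) stats::fft(x) / sqrt(length(x))

#' @keywords internal
ifftn_raw <- function(x) stats::fft(x, inverse = TRUE)

#' Recenter an FFT-native plane so DC sits at the array centre
#'
#' @param x A matrix in FFT-native order.
#' @param inverse Undo a previous shift (relevant for odd sizes).
#' @return Matrix of the same shape with the zero-frequency (or zero-lag)
#'   sample moved to `(floor(nrow/2)+1, floor(ncol/2)+1)`.
#' @export
fftshift2 <- function(x, inverse = FALSE) {
  sh <- function(n) if (inverse) ceiling(n / 2) else floor(n / 2)
  i <- (seq_len(nrow(x)) - 1L + nrow(x) - sh(nrow(x))) %% nrow(x) + 1L
  j <- (seq_len(ncol(x)) - 1L + ncol(x) - sh(ncol(x))) %% ncol(x) + 1L
  x[i, j, drop = FALSE]
}

# Circular shift of a matrix by integer pixels (positive = towards higher
# index), used to move templates between the centred and zero-lag frames.
#' @keywords internal
circshift2 <- function(x, dy, dx) {
  ny <- nrow(x); nx <- ncol(x)
  i <- ((seq_len(ny) - 1L - dy) %% ny) + 1L
  j <- ((seq_len(nx) - 1L - dx) %% nx) + 1L
  x[i, j, drop = FALSE]
}
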