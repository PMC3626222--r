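# The trainable nonlinear filter cascade: correlation layers with 2D
# spectral kernels, pointwise cubic-polynomial thresholds between layers,
# and a squared-modulus readout.

#' Cubic threshold coefficients
#'
#' Coefficients of the pointwise nonlinearity `a x^3 + b x^2 + c x + d`
#' applied between correlation layers.  The cascade stays complex until the
#' final modulus stage, so the polynomial acts on complex values and the
#' coefficients may be complex.
#'
#' @param a,b,c,d Complex (or numeric) scalars. Defaults give the identity.
#' @return An object of class `threshold_coeffs`.
#' @export
threshold_coeffs <- function(a = 0, b = 0, c = 1, d = 0) {
  v <- c(a = as.complex(a), b = as.complex(b), c = as.complex(c), d = as.complex(d))
  stopifnot(all(is.finite(Re(v))), all(is.finite(Im(v))))
  structure(as.list(v), class = "threshold_coeffs")
}

#' @export
print.threshold_coeffs <- function(x, ...) {
  cat(sprintf("<threshold_coeffs> a=%s b=%s c=%s d=%s\n",
              format(x$a), format(x$b), format(x$c), format(x$d)))
  invisible(x)
}

#' A trainable nonlinear correlation filter
#'
#' An ordered cascade of correlation layers, each a 2D [spectral_kernel()]
#' paired with [threshold_coeffs()], followed by an implicit squared-modulus
#' readout.  Only a compact `kernel_extent` block of spectral samples
#' around DC is trainable in each kernel; the rest of the grid is zero
#' padding, which keeps the effective kernel small relative to the image
#' and avoids wrap-around artefacts.  The z-dimension of every layer comes
#' from propagation phases, never from independently stored per-plane
#' kernels.
#'
#' @param kernels List of [spectral_kernel()], one per layer (>= 1).
#' @param thresholds List of [threshold_coeffs()], one per layer. Defaults
#'   to identity thresholds.
#' @param kernel_extent Integer `c(ky, kx)` size of the trainable spectral
#'   support. Default `c(16, 16)`.
#' @return An object of class `filter_model`.
#' @export
filter_model <- function(kernels, thresholds = NULL,
                         kernel_extent = c(16L, 16L)) {
  stopifnot(is.list(kernels), length(kernels) >= 1L)
  for (k in kernels) stopifnot(inherits(k, "spectral_kernel"))
  config <- kernels[[1]]$config
  for (k in kernels) stop_config_mismatch(k$config, config, "layer kernels")
  if (is.null(thresholds)) {
    thresholds <- replicate(length(kernels), threshold_coeffs(), simplify = FALSE)
  }
  stopifnot(length(thresholds) == length(kernels))
  for (t in thresholds) stopifnot(inherits(t, "threshold_coeffs"))
  kernel_extent <- as.integer(kernel_extent)
  stopifnot(length(kernel_extent) == 2L, all(kernel_extent >= 1L),
            kernel_extent[1] <= config$ny, kernel_extent[2] <= config$nx)
  structure(list(kernels = kernels, thresholds = thresholds,
                 kernel_extent = kernel_extent, config = config),
            class = "filter_model")
}

#' @export
print.filter_model <- function(x, ...) {
  cat(sprintf("<filter_model> %d layer(s), %d x %d trainable support on a %d x %d grid\n",
              length(x$kernels), x$kernel_extent[1], x$kernel_extent[2],
              x$config$ny, x$config$nx))
  invisible(x)
}

# Embed a small centered block into an ny x nx zero matrix (centered frame).
#' @keywords internal
embed_centered <- function(small, ny, nx) {
  sy <- nrow(small); sx <- ncol(small)
  stopifnot(sy <= ny, sx <= nx)
  out <- matrix(0 + 0i, ny, nx)
  cy <- floor(ny / 2) + 1L; cx <- floor(nx / 2) + 1L
  rows <- (cy - floor(sy / 2)):(cy - floor(sy / 2) + sy - 1L)
  cols <- (cx - floor(sx / 2)):(cx - floor(sx / 2) + sx - 1L)
  out[rows, cols] <- small
  out
}

#' @keywords internal
extract_centered <- function(x, sy, sx) {
  ny <- nrow(x); nx <- ncol(x)
  cy <- floor(ny / 2) + 1L; cx <- floor(nx / 2) + 1L
  rows <- (cy - floor(sy / 2)):(cy - floor(sy / 2) + sy - 1L)
  cols <- (cx - floor(sx / 2)):(cx - floor(sx / 2) + sx - 1L)
  x[rows, cols, drop = FALSE]
}

#' Zero-pad a small spectral support into a full kernel grid
#'
#' Embeds the trainable block of spectral samples, centered on DC, into the
#' configuration's full spectral grid (zeros elsewhere) and returns it as a
#' [spectral_kernel()].  [unpad_kernel()] recovers the block bit-exactly.
#'
#' @param kernel_small Complex matrix of the trainable support
#'   (`ky_size x kx_size`, DC at its centre element
#'   `(floor(ky/2)+1, floor(kx/2)+1)`).
#' @param config Target [optical_config()].
#' @return A [spectral_kernel()] on the full grid.
#' @export
pad_kernel <- function(kernel_small, config) {
  stopifnot(is.matrix(kernel_small), inherits(config, "optical_config"))
  if (nrow(kernel_small) > config$ny || ncol(kernel_small) > config$nx) {
    stop("kernel support larger than the spectral grid", call. = FALSE)
  }
  centered <- embed_centered(kernel_small, config$ny, config$nx)
  spectral_kernel(fftshift2(centered, inverse = TRUE), config)
}

#' Extract the trainable support of a padded kernel
#'
#' @param kernel A [spectral_kernel()].
#' @param extent Integer `c(ky, kx)` support size.
#' @return Complex matrix `ky x kx` (inverse of [pad_kernel()]).
#' @export
unpad_kernel <- function(kernel, extent) {
  stopifnot(inherits(kernel, "spectral_kernel"), length(extent) == 2L)
  extract_centered(fftshift2(kernel$values), extent[1], extent[2])
}

#' Correlation layer of the cascade
#'
#' For a [field_volume()] (a propagating field, always the first layer)
#' this is [correlate_volume()]: plane-wise 2D spectral filtering, equal
#' to the 3D correlation by the shell identity.  The identity's discrete
#' form says the space-domain kernel correlating each reconstructed plane
#' is one fixed, z-independent 2D kernel; later layers (whose inputs are
#' no longer propagating fields after a pointwise threshold) therefore
#' correlate every plane with that same kernel — the two paths coincide
#' exactly on propagating volumes, a delta kernel is exactly the
#' band-limited identity, and the trainable degrees of freedom stay 2D.
#'
#' @param x A [field_volume()], [correlation_volume()] or complex 3D array.
#' @param kernel A [spectral_kernel()] on the same config.
#' @param z_values Axial grid (µm); required only when `x` is a bare array.
#' @param config Required only when `x` is a bare array.
#' @return A [correlation_volume()].
#' @export
apply_correlation_op <- function(x, kernel, z_values = NULL, config = NULL) {
  stopifnot(inherits(kernel, "spectral_kernel"))
  if (inherits(x, "field_volume")) {
    return(correlate_volume(x, kernel))
  }
  if (inherits(x, "correlation_volume")) {
    z_values <- x$z_values
    config <- x$config
    planes <- x$planes
  } else if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(!is.null(z_values), !is.null(config))
    planes <- lapply(seq_len(dim(x)[3]), function(m) x[, , m])
  } else {
    stop("x must be a field_volume, correlation_volume or 3D array", call. = FALSE)
  }
  stop_config_mismatch(config, kernel$config, "input and kernel")
  stopifnot(length(z_values) == length(planes))
  Kc <- Conj(kernel$values)
  out <- lapply(planes, function(p) ifft2_unitary(fft2_unitary(p) * Kc))
  correlation_volume(out, z_values, config)
}

#' Pointwise cubic threshold
#'
#' Applies `a x^3 + b x^2 + c x + d` to every element.  Complex in, complex
#' out: the cascade keeps phase until the modulus stage.
#'
#' @param x A [correlation_volume()], complex array or matrix.
#' @param coeffs A [threshold_coeffs()].
#' @return Same container as `x`, thresholded elementwise.
#' @export
apply_threshold <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "threshold_coeffs"))
  f <- function(v) coeffs$a * v^3 + coeffs$b * v^2 + coeffs$c * v + coeffs$d
  if (inherits(x, "correlation_volume")) {
    x$planes <- lapply(x$planes, f)
    return(x)
  }
  f(x)
}

#' Squared-modulus readout
#'
#' The intensity `|x|^2` of every element: the final, real and nonnegative
#' stage of the cascade.
#'
#' @param x A [correlation_volume()], complex array or matrix.
#' @param z_values,config Used only when `x` is a bare array, to build the
#'   returned volume; optional.
#' @return For a `correlation_volume`, an [output_volume()]; otherwise a
#'   numeric array of the same shape.
#' @export
apply_modulus <- function(x, z_values = NULL, config = NULL) {
  if (inherits(x, "correlation_volume")) {
    vals <- vapply(x$planes, function(p) Mod(p)^2,
                   matrix(0, nrow(x$planes[[1]]), ncol(x$planes[[1]])))
    return(output_volume(array(vals, c(dim(x$planes[[1]]), length(x$planes))),
                         x$z_values, x$config))
  }
  Mod(x)^2
}

#' Real-valued filter output volume
#'
#' @param values Numeric `ny x nx x nz` array (nonnegative intensities).
#' @param z_values Axial grid (µm).
#' @param config The [optical_config()].
#' @return An object of class `output_volume`.
#' @export
output_volume <- function(values, z_values, config) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            dim(values)[3] == length(z_values),
            inherits(config, "optical_config"))
  structure(list(values = values, z_values = as.numeric(z_values),
                 config = config),
            class = "output_volume")
}

#' @export
print.output_volume <- function(x, ...) {
  cat(sprintf("<output_volume> %d x %d x %d, max %.6g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              max(x$values)))
  invisible(x)
}

#' Run the full nonlinear filter cascade
#'
#' For each layer in order: correlation ([apply_correlation_op()]) then
#' threshold ([apply_threshold()]); after the last layer the squared
#' modulus ([apply_modulus()]).  Output shape equals input shape; the
#' output is real and nonnegative, and circular x/y shifts of the input
#' shift the output identically.
#'
#' @param model A [filter_model()].
#' @param x A [field_volume()] sharing the model's config.
#' @return An [output_volume()].
#' @export
apply_filter <- function(model, x) {
  stopifnot(inherits(model, "filter_model"), inherits(x, "field_volume"))
  stop_config_mismatch(model$config, x$config, "model and input")
  if (length(model$kernels) == 0L) stop("empty filter model", call. = FALSE)
  cur <- x
  for (i in seq_along(model$kernels)) {
    cur <- apply_correlation_op(cur, model$kernels[[i]])
    cur <- apply_threshold(cur, model$thresholds[[i]])
  }
  apply_modulus(cur)
}

#' Transplant a filter kernel onto another grid at the same pitch
#'
#' A trained kernel lives on the spectral grid of its training volumes; to
#' filter a larger scene at the same pixel pitch, its space-domain impulse
#' response (a compact template-like kernel) is recentred, embedded into
#' the larger spatial grid and transformed back.  Correlation output values
#' are preserved up to the (small) impulse-response energy outside the
#' source grid.  The impulse response is assumed anchored at the zero-lag
#' origin — the convention of kernels trained on zero-lag-shifted
#' references; recentre a centred kernel before transplanting it.
#'
#' @param kernel A [spectral_kernel()].
#' @param config Target [optical_config()] with the same pixel pitch.
#' @return A [spectral_kernel()] on the target grid.
#' @export
resample_kernel <- function(kernel, config) {
  stopifnot(inherits(kernel, "spectral_kernel"), inherits(config, "optical_config"))
  src <- kernel$config
  if (abs(src$pixel_pitch - config$pixel_pitch) > 1e-12) {
    stop("resample_kernel requires matching pixel pitch", call. = FALSE)
  }
  if (config$ny < src$ny || config$nx < src$nx) {
    stop("target grid smaller than the kernel grid", call. = FALSE)
  }
  h <- impulse_response_at(kernel, 0)
  h_cent <- fftshift2(h)
  h_big <- embed_centered(h_cent, config$ny, config$nx)
  # preserve the spatial kernel samples exactly: correlation values are
  # plain spatial sums, so peaks carry over across grids.  The kernel
  # convention is the integral transform, H = sum_r h exp(-j2pi k.r).
  H <- stats::fft(fftshift2(h_big, inverse = TRUE))
  spectral_kernel(H, config)
}

#' Transplant every kernel of a model onto another grid
#'
#' @param model A [filter_model()].
#' @param config Target [optical_config()] with the same pixel pitch.
#' @return A [filter_model()] on the target grid (same thresholds and
#'   kernel extent).
#' @export
resample_filter_model <- function(model, config) {
  stopifnot(inherits(model, "filter_model"))
  filter_model(lapply(model$kernels, resample_kernel, config = config),
               model$thresholds, model$kernel_extent)
}
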