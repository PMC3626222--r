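# 3D correlation of propagating fields.
#
# The central identity: a monochromatic field has spectral support only on
# the Ewald shell, so a general 3D correlation kernel h(r) acting on it has
# effectively 2D degrees of freedom H(kx, ky).  One plane Z of the 3D
# correlation is the inverse 2D transform of U.H*.exp(j 2 pi Z kz) — a 2D
# circular correlation of the reconstructed plane with a fixed kernel.

#' A 2D spectral correlation kernel
#'
#' The kernel of a 3D correlation filter for propagating fields, stored as
#' its 2D transfer function over `(kx, ky)` at the z = 0 reference plane,
#' FFT-native order.  Its z-dependence is never stored: it is derived from
#' the propagation phase (see [impulse_response_at()]), which is exactly why
#' a 3D filter on a propagating field has only 2D degrees of freedom.
#'
#' Kernel values follow the integral (unnormalised) transform convention:
#' the space-domain kernel is `h = (1/N) sum_k H exp(+j2pi k.r)`, so an
#' all-pass kernel (`H = 1` over the band) is exactly the band-limited
#' identity, and a kernel whose impulse response equals a template is that
#' template's matched filter.
#'
#' @param values `ny x nx` complex matrix (FFT-native order).
#' @param config An [optical_config()].
#' @return An object of class `spectral_kernel`. Out-of-band entries are
#'   zeroed, as for [spectrum2d()].
#' @export
spectral_kernel <- function(values, config) {
  stopifnot(inherits(config, "optical_config"), is.matrix(values))
  if (!all(dim(values) == c(config$ny, config$nx))) {
    stop("kernel values must be a ny x nx matrix matching the config", call. = FALSE)
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("kernel values must be finite", call. = FALSE)
  }
  storage.mode(values) <- "complex"
  values[!band_mask(config)] <- 0 + 0i
  structure(list(values = values, config = config), class = "spectral_kernel")
}

#' @export
print.spectral_kernel <- function(x, ...) {
  cat(sprintf("<spectral_kernel> %d x %d, %d nonzero spectral samples\n",
              x$config$ny, x$config$nx, sum(x$values != 0)))
  invisible(x)
}

#' A stack of correlation output planes
#'
#' @param planes List of complex (or real) matrices, one per z.
#' @param z_values Axial grid (µm).
#' @param config The shared [optical_config()].
#' @return An object of class `correlation_volume`.
#' @export
correlation_volume <- function(planes, z_values, config) {
  stopifnot(is.list(planes), length(planes) == length(z_values),
            inherits(config, "optical_config"))
  structure(list(planes = planes, z_values = as.numeric(z_values),
                 config = config),
            class = "correlation_volume")
}

#' @export
print.correlation_volume <- function(x, ...) {
  cat(sprintf("<correlation_volume> %d planes of %d x %d\n",
              length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]])))
  invisible(x)
}

#' One plane of the 3D correlation
#'
#' Evaluates the plane `z` of the 3D correlation of a propagating field
#' (given by its shell spectrum) with a kernel: the unitary inverse
#' transform of `U . H* . exp(+j 2 pi z kz)`.  Zero lag is at index
#' `[1, 1]`; use [fftshift2()] to recenter for display.  The result equals
#' the 2D circular cross-correlation `sum_m u_z(m) conj(h(m - r))` of the
#' reconstructed plane `u_z` with the space-domain kernel, and also the
#' plane-`z` slice of the full 3D correlation (see
#' [brute_force_correlate3d()]).
#'
#' @param spec A [spectrum2d()] (shell convention, reference z = 0).
#' @param kernel A [spectral_kernel()] on the same config.
#' @param z Output plane (µm).
#' @return `ny x nx` complex matrix.
#' @export
correlate_plane <- function(spec, kernel, z = 0) {
  stopifnot(inherits(spec, "spectrum2d"), inherits(kernel, "spectral_kernel"))
  stop_config_mismatch(spec$config, kernel$config, "spectrum and kernel")
  g <- kz_grid(spec$config)
  ifft2_unitary(spec$values * Conj(kernel$values) * exp(2i * pi * z * g$kz))
}

#' Space-domain impulse response of a kernel at axial lag z
#'
#' The 2D kernel whose circular cross-correlation with the measured plane
#' (z = 0) reproduces [correlate_plane()] at plane `z`: the integral-
#' convention inverse transform `(1/N) sum_k H exp(-j 2 pi z kz) exp(+j 2
#' pi k.r)`.  Its z-dependence is a pure
#' spectral phase, so its energy is independent of `z`.  The stack of these
#' planes over a z grid is itself a propagating field — the 3D impulse
#' response of the filter.
#'
#' @param kernel A [spectral_kernel()].
#' @param z Axial lag (µm).
#' @return `ny x nx` complex matrix (space domain, zero lag at `[1, 1]`).
#' @export
impulse_response_at <- function(kernel, z = 0) {
  stopifnot(inherits(kernel, "spectral_kernel"))
  g <- kz_grid(kernel$config)
  ifft2_raw(kernel$values * exp(-2i * pi * z * g$kz)) / length(kernel$values)
}

#' 3D correlation of a reconstructed volume, plane by plane
#'
#' Computes the shell spectrum once (from the first plane; any plane of a
#' consistent volume gives the same spectrum) and applies
#' [correlate_plane()] at every z of the volume grid.
#'
#' @param volume A [field_volume()].
#' @param kernel A [spectral_kernel()] on the same config.
#' @return A [correlation_volume()] on the same z grid.
#' @export
correlate_volume <- function(volume, kernel) {
  stopifnot(inherits(volume, "field_volume"), inherits(kernel, "spectral_kernel"))
  stop_config_mismatch(volume$config, kernel$config, "volume and kernel")
  if (length(volume$planes) == 0L) stop("empty volume", call. = FALSE)
  spec <- field_to_spectrum(volume$planes[[1]])
  planes <- lapply(volume$z_values, function(z) correlate_plane(spec, kernel, z))
  correlation_volume(planes, volume$z_values, volume$config)
}

#' Literal triple-sum 3D correlation (test oracle)
#'
#' Direct evaluation of the 3D cross-correlation
#' `R(r) = sum_x u(x) conj(h(x - r))` of a reconstructed volume with the
#' kernel's 3D impulse response, with no spectral shortcut in x/y: every
#' lateral shift is an explicit elementwise sum with circular x/y indexing.
#' The kernel volume is built by [impulse_response_at()] at the true axial
#' lags `z_p - z_m` (the impulse response is defined for every z by the
#' propagation phase, so the axial sum follows the kernel's native
#' continuation rather than a periodic wrap), and the axial sum is
#' normalised by `1/nz`, the discrete surrogate of the shell-delta
#' integration.  Numerically equal to [correlate_volume()]; kept deliberately
#' slow and restricted to small grids.
#'
#' @param volume A [field_volume()], at most 16 x 16 x 8.
#' @param kernel A [spectral_kernel()] on the same config.
#' @return A [correlation_volume()].
#' @export
brute_force_correlate3d <- function(volume, kernel) {
  stopifnot(inherits(volume, "field_volume"), inherits(kernel, "spectral_kernel"))
  stop_config_mismatch(volume$config, kernel$config, "volume and kernel")
  ny <- volume$config$ny; nx <- volume$config$nx; nz <- length(volume$planes)
  if (ny > 16 || nx > 16 || nz > 8) {
    stop("brute_force_correlate3d is a test oracle; grids above 16 x 16 x 8 are refused",
         call. = FALSE)
  }
  u <- volume_array(volume)
  out <- vector("list", nz)
  for (p in seq_len(nz)) {
    Rp <- matrix(0 + 0i, ny, nx)
    for (m in seq_len(nz)) {
      # kernel plane at the true axial lag z_p - z_m
      h <- impulse_response_at(kernel, volume$z_values[p] - volume$z_values[m])
      hc <- Conj(h)
      um <- u[, , m]
      for (ry in 0:(ny - 1)) {
        for (rx in 0:(nx - 1)) {
          # circular lateral shift of the kernel by (ry, rx)
          Rp[ry + 1, rx + 1] <- Rp[ry + 1, rx + 1] +
            sum(um * circshift2(hc, ry, rx))
        }
      }
    }
    out[[p]] <- Rp / nz
  }
  correlation_volume(out, volume$z_values, volume$config)
}
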