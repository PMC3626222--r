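#' A monochromatic complex-amplitude plane
#'
#' One 2D complex field sampled at axial position `z`, tied to an
#' [optical_config()].  Values are dimensionless amplitudes relative to the
#' unit illumination wave.
#'
#' @param values `ny x nx` complex (or numeric) matrix.
#' @param config An [optical_config()] whose grid matches `values`.
#' @param z Axial position of the plane (µm). The axis increases away from
#'   the objective, origin at the nominal focus.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, config, z = 0) {
  stopifnot(inherits(config, "optical_config"), is.matrix(values),
            is.numeric(z), length(z) == 1L, is.finite(z))
  if (!all(dim(values) == c(config$ny, config$nx))) {
    stop("field values must be a ny x nx matrix matching the config", call. = FALSE)
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("field values must be finite", call. = FALSE)
  }
  storage.mode(values) <- "complex"
  structure(list(values = values, z = as.numeric(z), config = config),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at z = %.4g um; energy %.6g\n",
              x$config$ny, x$config$nx, x$z, sum(Mod(x$values)^2)))
  invisible(x)
}

#' The angular spectrum of a propagating field
#'
#' Complex spectral samples over `(kx, ky)` in FFT-native order, referred to
#' the shell convention: the stored values are those of the z-independent
#' spectrum projected from the Ewald sphere, so that the field at any plane
#' `z` is the inverse transform of `values * exp(+j 2 pi z kz)`.  Entries
#' outside the propagating band or the aperture band are exactly zero.
#'
#' @param values `ny x nx` complex matrix (FFT-native order).
#' @param config An [optical_config()].
#' @param reference_z Axial position (µm) of the plane the spectrum was
#'   measured at (metadata; the values themselves are z-independent).
#' @return An object of class `spectrum2d`.
#' @export
spectrum2d <- function(values, config, reference_z = 0) {
  stopifnot(inherits(config, "optical_config"), is.matrix(values))
  if (!all(dim(values) == c(config$ny, config$nx))) {
    stop("spectrum values must be a ny x nx matrix matching the config", call. = FALSE)
  }
  storage.mode(values) <- "complex"
  values[!band_mask(config)] <- 0 + 0i
  structure(list(values = values, config = config,
                 reference_z = as.numeric(reference_z)),
            class = "spectrum2d")
}

#' An ordered stack of reconstructed planes
#'
#' @param planes List of [complex_field()] objects sharing one config.
#' @param z_values Strictly increasing axial grid (µm), one per plane.
#' @return An object of class `field_volume` with elements `planes`,
#'   `z_values`, `config`.
#' @export
field_volume <- function(planes, z_values) {
  stopifnot(is.list(planes), length(planes) >= 1L,
            length(planes) == length(z_values))
  if (any(diff(z_values) <= 0)) {
    stop("z_values must be strictly increasing", call. = FALSE)
  }
  config <- planes[[1]]$config
  for (p in planes) {
    stopifnot(inherits(p, "complex_field"))
    stop_config_mismatch(p$config, config, "volume planes")
  }
  structure(list(planes = planes, z_values = as.numeric(z_values),
                 config = config),
            class = "field_volume")
}

#' @export
print.field_volume <- function(x, ...) {
  cat(sprintf("<field_volume> %d planes of %d x %d, z in [%.4g, %.4g] um\n",
              length(x$planes), x$config$ny, x$config$nx,
              min(x$z_values), max(x$z_values)))
  invisible(x)
}

#' Convert a field volume to a plain 3D array
#'
#' @param volume A [field_volume()] (or a `correlation_volume`).
#' @return Complex (or numeric) array `ny x nx x nz`.
#' @export
volume_array <- function(volume) {
  vals <- lapply(volume$planes, function(p) if (is.list(p)) p$values else p)
  array(unlist(vals), dim = c(dim(vals[[1]]), length(vals)))
}

#' Angular spectrum of a measured plane
#'
#' Forward 2D transform of the plane, referred to the shell convention by
#' the phase `exp(-j 2 pi z kz)` so the returned spectrum is independent of
#' the plane the field was measured at.  Evanescent and aperture cutoffs are
#' applied.  Inverse of [spectrum_to_field()] at the same `z`, up to the
#' energy removed by the cutoffs.
#'
#' @param field A [complex_field()].
#' @return A [spectrum2d()].
#' @export
field_to_spectrum <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  cfg <- field$config
  U <- fft2_unitary(field$values)
  g <- kz_grid(cfg)
  U <- U * exp(-2i * pi * field$z * g$kz)
  spectrum2d(U, cfg, reference_z = field$z)
}

#' Field at an arbitrary parallel plane
#'
#' Evaluates the plane `z` of the propagating field from its shell spectrum:
#' inverse transform of `values * exp(+j 2 pi z kz)`.  Propagation is a pure
#' spectral phase, so in-band energy is conserved for every `z`.
#'
#' @param spec A [spectrum2d()].
#' @param z Target axial position (µm).
#' @return A [complex_field()] at `z`.
#' @export
spectrum_to_field <- function(spec, z) {
  stopifnot(inherits(spec, "spectrum2d"), is.numeric(z), length(z) == 1L)
  cfg <- spec$config
  g <- kz_grid(cfg)
  u <- ifft2_unitary(spec$values * exp(2i * pi * z * g$kz))
  complex_field(u, cfg, z = z)
}

#' Propagate a field to another plane
#'
#' Convenience composition of [field_to_spectrum()] and
#' [spectrum_to_field()].
#'
#' @param field A [complex_field()].
#' @param z Target plane (µm).
#' @return A [complex_field()] at `z`.
#' @export
propagate_field <- function(field, z) {
  spectrum_to_field(field_to_spectrum(field), z)
}

#' Reconstruct a volume from a single measured plane
#'
#' One plane of a propagating monochromatic field determines the whole
#' volume: the spectrum is computed once and evaluated at every requested
#' plane.  All reconstructed planes are therefore mutually consistent under
#' propagation.
#'
#' @param field A [complex_field()] (the measured plane).
#' @param z_values Strictly increasing axial positions (µm).
#' @return A [field_volume()].
#' @examples
#' cfg <- optical_config(pixel_pitch = 0.25, nx = 32)
#' u0 <- complex_field(matrix(1 + 0i, 32, 32), cfg)
#' vol <- reconstruct_volume(u0, seq(-2, 2, length.out = 8))
#' @export
reconstruct_volume <- function(field, z_values) {
  stopifnot(inherits(field, "complex_field"))
  if (length(z_values) == 0L) {
    stop("no reconstruction requested: z_values is empty", call. = FALSE)
  }
  if (any(diff(z_values) <= 0)) {
    stop("z_values must be strictly increasing", call. = FALSE)
  }
  spec <- field_to_spectrum(field)
  planes <- lapply(z_values, function(z) spectrum_to_field(spec, z))
  field_volume(planes, z_values)
}

#' Subtract the undiffracted illumination wave from a spectrum
#'
#' Removes the known background (a unit-amplitude plane wave, or the
#' reference-normalised equivalent after hologram demodulation) from the
#' DC spectral bin, leaving the scattered field only — including the
#' scattered field's own mean, which carries each object's total
#' scattering strength.  Correlation filtering operates on this scattered
#' component: the unfiltered background otherwise adds a constant,
#' object-independent term to every output plane.  Applied identically
#' when building training references and inside the detection pipeline.
#'
#' @param spec A [spectrum2d()].
#' @param background Complex amplitude of the illumination wave. Default 1.
#' @return The spectrum with the background's DC contribution removed.
#' @export
subtract_background <- function(spec, background = 1 + 0i) {
  stopifnot(inherits(spec, "spectrum2d"))
  # a constant plane of amplitude A transforms to A*sqrt(N) in the DC bin
  spec$values[1, 1] <- spec$values[1, 1] -
    background * sqrt(spec$config$nx * spec$config$ny)
  spec
}

#' In-band energy of a field or spectrum
#'
#' @param x A [complex_field()], [spectrum2d()] or matrix.
#' @return Sum of squared moduli (for a field, after band limiting it is
#'   identical at every propagation distance).
#' @export
field_energy <- function(x) {
  v <- if (is.list(x)) x$values else x
  sum(Mod(v)^2)
}
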