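#' Optical configuration of a holographic recording
#'
#' Bundles the quantities that define the spectral grids every other object
#' in the package lives on: wavelength, object-plane sampling pitch, grid
#' size, numerical aperture and the refractive index of the suspension
#' medium.  All lengths are in microns; spatial frequencies are in
#' cycles/µm with the wave number defined as `k = 1/lambda`.
#'
#' The propagating band is limited twice: components with
#' `kx^2 + ky^2 > (medium_index/lambda)^2` are evanescent and discarded, and
#' components with `kx^2 + ky^2 > (NA/lambda)^2` fall outside the objective
#' aperture and are discarded as well.  If the pixel pitch undersamples the
#' aperture band (`pixel_pitch > lambda/(2 NA)`) a warning is raised — the
#' configuration is still usable, the grid Nyquist limit simply becomes the
#' effective band edge.
#'
#' @param wavelength Vacuum wavelength (µm). Default 0.633 (He-Ne laser).
#' @param pixel_pitch Object-plane sample spacing (µm).
#' @param nx,ny Samples per plane along x (columns) and y (rows).
#' @param numerical_aperture Objective NA. Default 1.25.
#' @param medium_index Refractive index of the medium (>= 1). Default 1.33
#'   (water; the organisms are imaged in suspension).
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(pixel_pitch = 0.25, nx = 64, ny = 64)
#' cfg
#' @export
optical_config <- function(wavelength = 0.633, pixel_pitch, nx, ny = nx,
                           numerical_aperture = 1.25, medium_index = 1.33) {
  stopifnot(
    is.numeric(wavelength), length(wavelength) == 1L, wavelength > 0,
    is.numeric(pixel_pitch), length(pixel_pitch) == 1L, pixel_pitch > 0,
    nx == as.integer(nx), nx >= 1, ny == as.integer(ny), ny >= 1,
    is.numeric(numerical_aperture), numerical_aperture > 0,
    is.numeric(medium_index), medium_index >= 1
  )
  if (pixel_pitch > wavelength / (2 * numerical_aperture)) {
    warning(sprintf(
      "pixel_pitch %.4g um undersamples the NA-limited band (Nyquist pitch %.4g um); the grid Nyquist limit becomes the effective band edge",
      pixel_pitch, wavelength / (2 * numerical_aperture)
    ), call. = FALSE)
  }
  structure(
    list(
      wavelength = as.numeric(wavelength),
      pixel_pitch = as.numeric(pixel_pitch),
      nx = as.integer(nx), ny = as.integer(ny),
      numerical_aperture = as.numeric(numerical_aperture),
      medium_index = as.numeric(medium_index)
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength    : %.4g um\n", x$wavelength))
  cat(sprintf("  pixel pitch   : %.4g um  (field %g x %g um)\n",
              x$pixel_pitch, x$nx * x$pixel_pitch, x$ny * x$pixel_pitch))
  cat(sprintf("  grid          : %d x %d (nx x ny)\n", x$nx, x$ny))
  cat(sprintf("  NA            : %.3g   medium index: %.3g\n",
              x$numerical_aperture, x$medium_index))
  invisible(x)
}

#' @keywords internal
same_config <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' @keywords internal
stop_config_mismatch <- function(a, b, what = "objects") {
  if (!same_config(a, b)) {
    stop(sprintf("optical configurations of the %s do not match", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Spatial-frequency grids of a configuration
#'
#' Returns matrices of `kx`, `ky` (cycles/µm) in FFT-native order, shaped
#' `ny x nx` like every plane in the package.
#'
#' @param config An [optical_config()].
#' @return List with matrices `kx`, `ky` and `kr2 = kx^2 + ky^2`.
#' @keywords internal
freq_grid <- function(config) {
  kx <- fft_freq(config$nx, config$pixel_pitch)
  ky <- fft_freq(config$ny, config$pixel_pitch)
  KX <- matrix(kx, nrow = config$ny, ncol = config$nx, byrow = TRUE)
  KY <- matrix(ky, nrow = config$ny, ncol = config$nx)
  list(kx = KX, ky = KY, kr2 = KX^2 + KY^2)
}

#' Axial spatial frequency grid with evanescent mask
#'
#' Evaluates `kz = sqrt((n/lambda)^2 - kx^2 - ky^2)` on the spectral grid,
#' taking the positive root only (forward-propagating flux).  Where the
#' radicand is negative the wave is evanescent: `kz` is set to 0 and the
#' mask flags the entry as non-propagating.
#'
#' @param config An [optical_config()].
#' @return List with `kz` (`ny x nx` matrix, cycles/µm) and `propagating`
#'   (logical matrix, `TRUE` where the component propagates).
#' @examples
#' g <- kz_grid(optical_config(pixel_pitch = 0.25, nx = 16,
#'                             medium_index = 1))
#' g$kz[1, 1] * 0.633  # on-axis component: kz = 1/lambda
#' @export
kz_grid <- function(config) {
  fg <- freq_grid(config)
  rad <- (config$medium_index / config$wavelength)^2 - fg$kr2
  propagating <- rad >= 0
  kz <- sqrt(pmax(rad, 0))
  list(kz = kz, propagating = propagating)
}

#' In-band mask: propagating and inside the objective aperture
#'
#' @param config An [optical_config()].
#' @return Logical `ny x nx` matrix, `TRUE` where `kx^2 + ky^2` is within
#'   both the evanescent limit `(n/lambda)^2` and the aperture limit
#'   `(NA/lambda)^2`.
#' @export
band_mask <- function(config) {
  fg <- freq_grid(config)
  lim_ev <- (config$medium_index / config$wavelength)^2
  lim_na <- (config$numerical_aperture / config$wavelength)^2
  fg$kr2 <= lim_ev & fg$kr2 <= lim_na
}
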