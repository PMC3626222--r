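# Synthetic microorganism scenes: rod-shaped weak phase objects of two
# size classes at random 3D positions and in-plane orientations, composed
# in first-Born fashion on a unit illumination wave, with optional
# off-axis hologram simulation and Fourier-side-band demodulation.

#' Geometry and transmittance of one rod-shaped organism
#'
#' A rod is a capsule (rectangle with semicircular caps) of complex
#' transmittance `amplitude * exp(j phase)` inside, 1 outside, rotated
#' in-plane.  The two classes model two rod-shaped species of similar
#' shape but slightly different size; the default dimensions and the weak
#' phase-object transmittance are invented values chosen once (no
#' published dimensions exist for the experiment being emulated) and are
#' stamped into generated scene files.
#'
#' @param class_label `"in"` (target species) or `"out"` (to be ignored).
#' @param length Rod length (µm), tip to tip. Defaults: 2.0 in-class,
#'   1.4 out-of-class.
#' @param width Rod width (µm), `length >= width > 0`. Defaults: 0.8
#'   in-class, 0.7 out-of-class.
#' @param orientation In-plane angle (degrees).
#' @param amplitude_transmittance Amplitude factor in `[0, 1]`. Default 0.95.
#' @param phase_shift Phase delay (radians). Default 0.5 (a weak phase
#'   object, the regime the linear first-Born composition assumes).
#' @return An object of class `rod_spec`.
#' @export
rod_spec <- function(class_label = "in",
                     length = if (class_label == "in") 2.0 else 1.4,
                     width = if (class_label == "in") 0.8 else 0.7,
                     orientation = 0,
                     amplitude_transmittance = 0.95,
                     phase_shift = 0.5) {
  stopifnot(class_label %in% c("in", "out"),
            is.numeric(length), is.numeric(width),
            length >= width, width > 0,
            amplitude_transmittance >= 0, amplitude_transmittance <= 1)
  structure(list(class_label = class_label, length = as.numeric(length),
                 width = as.numeric(width), orientation = as.numeric(orientation),
                 amplitude_transmittance = as.numeric(amplitude_transmittance),
                 phase_shift = as.numeric(phase_shift)),
            class = "rod_spec")
}

#' @export
print.rod_spec <- function(x, ...) {
  cat(sprintf("<rod_spec> %s-class %.2g x %.2g um at %g deg\n",
              x$class_label, x$length, x$width, x$orientation))
  invisible(x)
}

#' Render a rod's complex object function
#'
#' Transmission-mode object function on the configuration grid: 1 outside
#' the rod, `amplitude * exp(j phase)` inside, with one-pixel anti-aliased
#' edges (linear coverage ramp on the capsule's signed distance).
#'
#' @param spec A [rod_spec()].
#' @param config An [optical_config()].
#' @param center Rod centre `c(x, y)` in µm (field origin at grid centre).
#' @return `ny x nx` complex matrix.
#' @export
render_rod <- function(spec, config, center = c(0, 0)) {
  stopifnot(inherits(spec, "rod_spec"), inherits(config, "optical_config"))
  if (spec$length >= min(config$nx, config$ny) * config$pixel_pitch) {
    stop("rod larger than the field grid", call. = FALSE)
  }
  1 + rod_coverage(spec, config, center) *
    (spec$amplitude_transmittance * exp(1i * spec$phase_shift) - 1)
}

# Anti-aliased capsule coverage in [0, 1] on the field grid.
#' @keywords internal
rod_coverage <- function(spec, config, center = c(0, 0)) {
  nx <- config$nx; ny <- config$ny; p <- config$pixel_pitch
  x <- (seq_len(nx) - (floor(nx / 2) + 1)) * p
  y <- (seq_len(ny) - (floor(ny / 2) + 1)) * p
  X <- matrix(x, ny, nx, byrow = TRUE) - center[1]
  Y <- matrix(y, ny, nx) - center[2]
  th <- spec$orientation * pi / 180
  U <- cos(th) * X + sin(th) * Y
  V <- -sin(th) * X + cos(th) * Y
  hl <- (spec$length - spec$width) / 2
  d <- sqrt(pmax(abs(U) - hl, 0)^2 + V^2)  # distance to the capsule spine
  cov <- pmin(1, pmax(0, 0.5 + (spec$width / 2 - d) / p))
  matrix(cov, ny, nx)  # pmin/pmax drop dims when the first arg is scalar
}

#' A set of rods placed in a 3D field volume
#'
#' @param rods List of `list(spec = rod_spec, position = c(x, y, z))`
#'   entries, positions in µm (lateral origin at the field centre, z = 0
#'   at the focal plane).
#' @param config An [optical_config()].
#' @return An object of class `scene_placement`. Overlapping supports
#'   (3D centre separation below the mean rod length) or positions outside
#'   the field are refused.
#' @export
scene_placement <- function(rods, config) {
  stopifnot(is.list(rods), inherits(config, "optical_config"))
  half_x <- config$nx * config$pixel_pitch / 2
  half_y <- config$ny * config$pixel_pitch / 2
  for (r in rods) {
    stopifnot(inherits(r$spec, "rod_spec"), length(r$position) == 3L)
    if (abs(r$position[1]) > half_x || abs(r$position[2]) > half_y) {
      stop("rod position outside the field extent", call. = FALSE)
    }
  }
  if (length(rods) >= 2L) {
    for (i in seq_len(length(rods) - 1L)) {
      for (j in (i + 1L):length(rods)) {
        d <- sqrt(sum((rods[[i]]$position - rods[[j]]$position)^2))
        min_d <- (rods[[i]]$spec$length + rods[[j]]$spec$length) / 2
        if (d < min_d) stop("overlapping rod supports in the scene", call. = FALSE)
      }
    }
  }
  structure(list(rods = rods, config = config,
                 field_extent = c(config$nx, config$ny) * config$pixel_pitch),
            class = "scene_placement")
}

#' @export
print.scene_placement <- function(x, ...) {
  lab <- vapply(x$rods, function(r) r$spec$class_label, character(1))
  cat(sprintf("<scene_placement> %d rods (%d in-class, %d out-of-class) in %g x %g um\n",
              length(x$rods), sum(lab == "in"), sum(lab == "out"),
              x$field_extent[1], x$field_extent[2]))
  invisible(x)
}

#' Randomly placed two-class scene
#'
#' Rejection-samples non-overlapping 3D positions and random in-plane
#' orientations for the two rod classes, keeping a lateral margin so no
#' rod wraps across the periodic field boundary.
#'
#' @param n_inclass,n_outclass Rod counts per class.
#' @param config An [optical_config()].
#' @param z_range Axial placement interval (µm). Default `c(-4, 4)`.
#' @param margin Lateral clearance from the field edge (µm). Default: the
#'   in-class rod length.
#' @param seed Integer RNG seed.
#' @param ... Passed to [rod_spec()] (e.g. transmittance overrides).
#' @return A [scene_placement()].
#' @export
random_scene <- function(n_inclass, n_outclass, config, z_range = c(-4, 4),
                         margin = NULL, seed = 1L, ...) {
  stopifnot(n_inclass >= 0, n_outclass >= 0, n_inclass + n_outclass >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  if (is.null(margin)) margin <- rod_spec("in", ...)$length
  half_x <- config$nx * config$pixel_pitch / 2 - margin
  half_y <- config$ny * config$pixel_pitch / 2 - margin
  stopifnot(half_x > 0, half_y > 0)
  labels <- c(rep("in", n_inclass), rep("out", n_outclass))
  rods <- list()
  for (lab in labels) {
    spec <- rod_spec(lab, orientation = stats::runif(1, 0, 180), ...)
    for (try in seq_len(2000L)) {
      pos <- c(stats::runif(1, -half_x, half_x),
               stats::runif(1, -half_y, half_y),
               stats::runif(1, z_range[1], z_range[2]))
      ok <- all(vapply(rods, function(r) {
        sqrt(sum((r$position - pos)^2)) >= (r$spec$length + spec$length) / 2
      }, logical(1)))
      if (ok) break
      if (try == 2000L) stop("could not place rods without overlap", call. = FALSE)
    }
    rods[[length(rods) + 1L]] <- list(spec = spec, position = pos)
  }
  scene_placement(rods, config)
}

#' Render the complex amplitude of a scene at the focal plane
#'
#' Each rod's object function is imprinted on the unit illumination wave at
#' its own plane; the scattered perturbations `(o - 1)` are propagated to
#' z = 0 through the angular spectrum and summed on the unit background —
#' the first-Born (single-scattering) composition appropriate to weak
#' phase objects.
#'
#' @param placement A [scene_placement()].
#' @return A [complex_field()] at z = 0.
#' @export
render_scene <- function(placement) {
  stopifnot(inherits(placement, "scene_placement"))
  cfg <- placement$config
  g <- kz_grid(cfg)
  acc <- matrix(0 + 0i, cfg$ny, cfg$nx)
  for (r in placement$rods) {
    o <- render_rod(r$spec, cfg, center = r$position[1:2])
    # refer the perturbation's spectrum from its plane z to the shell
    acc <- acc + fft2_unitary(o - 1) * exp(-2i * pi * r$position[3] * g$kz)
  }
  acc[!band_mask(cfg)] <- 0 + 0i
  complex_field(matrix(1 + 0i, cfg$ny, cfg$nx) + ifft2_unitary(acc), cfg, z = 0)
}

#' Simulate an off-axis interferogram
#'
#' Intensity of the object field interfering with a tilted plane reference
#' wave: `I = |u + r exp(j 2 pi (fx x + fy y))|^2`.  The spatial carrier
#' must exceed twice the object band limit so the image side-band is
#' separable from the autocorrelation terms around DC (clean recovery
#' additionally wants three band radii — see [demodulate_hologram()]), and
#' must stay within the grid Nyquist limit.
#'
#' @param field A [complex_field()].
#' @param carrier Carrier frequency `c(fx, fy)` (cycles/µm).
#' @param reference_amplitude Reference wave amplitude. Default 1.
#' @param noise_sd Optional additive Gaussian intensity noise (standard
#'   deviation, same units as the interferogram). Default 0 (off).
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @return `ny x nx` real, nonnegative matrix (plus noise if requested).
#' @export
simulate_hologram <- function(field, carrier, reference_amplitude = 1,
                              noise_sd = 0, seed = 1L) {
  stopifnot(inherits(field, "complex_field"), length(carrier) == 2L,
            reference_amplitude > 0)
  cfg <- field$config
  B <- cfg$numerical_aperture / cfg$wavelength
  fc <- sqrt(sum(carrier^2))
  if (fc <= 2 * B) {
    stop("carrier too slow: |carrier| must exceed twice the NA band limit", call. = FALSE)
  }
  nyq <- 1 / (2 * cfg$pixel_pitch)
  if (any(abs(carrier) > nyq)) {
    stop("carrier exceeds the grid Nyquist limit", call. = FALSE)
  }
  ph <- carrier_phase(cfg, carrier)
  I <- Mod(field$values + reference_amplitude * exp(1i * ph))^2
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    I <- I + matrix(stats::rnorm(length(I), 0, noise_sd), nrow(I), ncol(I))
  }
  I
}

#' @keywords internal
carrier_phase <- function(config, carrier) {
  x <- (seq_len(config$nx) - (floor(config$nx / 2) + 1)) * config$pixel_pitch
  y <- (seq_len(config$ny) - (floor(config$ny / 2) + 1)) * config$pixel_pitch
  2 * pi * (matrix(x, config$ny, config$nx, byrow = TRUE) * carrier[1] +
              matrix(y, config$ny, config$nx) * carrier[2])
}

#' Recover the complex field from an off-axis interferogram
#'
#' Fourier side-band demodulation: the interferogram is mixed down by the
#' conjugate carrier, low-passed to the NA band, and divided by the
#' reference amplitude.  Recovery is exact within the band when the carrier
#' exceeds three band radii (so the autocorrelation term around DC misses
#' the passband entirely) and lies on the spectral grid — an integer number
#' of fringes across the field.  Off-grid carriers leak through the
#' periodic window (percent-level error); the image side-band itself is
#' demodulated exactly either way because the mixing happens in the space
#' domain.
#'
#' @param interferogram Real `ny x nx` matrix.
#' @param carrier Carrier `c(fx, fy)` used at recording (cycles/µm).
#' @param config The [optical_config()] of the recording.
#' @param reference_amplitude Reference amplitude used at recording.
#' @return A [complex_field()] at z = 0.
#' @export
demodulate_hologram <- function(interferogram, carrier, config,
                                reference_amplitude = 1) {
  stopifnot(is.matrix(interferogram), inherits(config, "optical_config"),
            length(carrier) == 2L, reference_amplitude > 0)
  B <- config$numerical_aperture / config$wavelength
  if (sqrt(sum(carrier^2)) <= 2 * B) {
    stop("side-band overlaps DC: carrier must exceed twice the NA band limit",
         call. = FALSE)
  }
  mixed <- interferogram * exp(1i * carrier_phase(config, carrier))
  S <- fft2_unitary(mixed)
  S[!band_mask(config)] <- 0 + 0i
  complex_field(ifft2_unitary(S) / reference_amplitude, config, z = 0)
}

#' Build a two-class training set of reconstructed rod volumes
#'
#' Emulates reference-set construction by rotation: rods of the two size
#' classes are rendered at the focal plane, their orientations advancing in
#' 45-degree steps (cycling through `rotations` of them), with a small
#' seeded size jitter standing in for natural cell-to-cell variation.
#' Each reference is shifted to the zero-lag frame (so the desired delta
#' sits at the first lexicographic voxel), background-subtracted, and reconstructed
#' as a [field_volume()] over `nz` planes starting at its own focal plane.
#'
#' @param n_inclass,n_outclass Reference counts. Defaults 25 and 17.
#' @param volume_shape Integer `c(ny, nx, nz)`. Default `c(32, 32, 16)`.
#' @param rotations Number of 45-degree orientation steps cycled through.
#'   Default 8.
#' @param rng_seed Integer seed controlling the size jitter.
#' @param config Optional [optical_config()]; defaults to a 0.25 µm pitch
#'   grid of the requested shape (He-Ne illumination, NA 1.25, water).
#' @param dz Axial plane spacing of the reference volumes (µm). Default 0.5.
#' @param size_jitter Relative s.d. of rod length/width jitter. Default 0.05.
#' @param ... Passed to [rod_spec()].
#' @return A [training_set()] with a `meta` tibble describing every rod.
#' @export
build_training_set <- function(n_inclass = 25L, n_outclass = 17L,
                               volume_shape = c(32L, 32L, 16L),
                               rotations = 8L, rng_seed = 1L,
                               config = NULL, dz = 0.5,
                               size_jitter = 0.05, ...) {
  stopifnot(n_inclass >= 1L, n_outclass >= 0L, rotations >= 1L,
            length(volume_shape) == 3L)
  if (is.null(config)) {
    config <- optical_config(pixel_pitch = 0.25,
                             nx = volume_shape[2], ny = volume_shape[1])
  }
  stopifnot(config$ny == volume_shape[1], config$nx == volume_shape[2])
  proto <- rod_spec("in", ...)
  if (proto$length >= min(config$nx, config$ny) * config$pixel_pitch) {
    stop("volume_shape too small for the rod dimensions", call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(rng_seed)

  labels <- c(rep("in", n_inclass), rep("out", n_outclass))
  zv <- (seq_len(volume_shape[3]) - 1) * dz
  g <- kz_grid(config)
  fg <- freq_grid(config)
  # integer-pixel shift from the grid centre to the zero-lag origin
  sx <- (floor(config$nx / 2)) * config$pixel_pitch
  sy <- (floor(config$ny / 2)) * config$pixel_pitch
  shift_phase <- exp(2i * pi * (fg$kx * sx + fg$ky * sy))

  refs <- vector("list", length(labels))
  meta_len <- meta_wid <- meta_ang <- numeric(length(labels))
  for (i in seq_along(labels)) {
    ang <- ((i - 1L) %% rotations) * 45
    jit <- 1 + stats::rnorm(2, 0, size_jitter)
    base <- rod_spec(labels[i], orientation = ang, ...)
    spec_i <- rod_spec(labels[i], length = base$length * jit[1],
                       width = min(base$width * jit[2], base$length * jit[1]),
                       orientation = ang,
                       amplitude_transmittance = base$amplitude_transmittance,
                       phase_shift = base$phase_shift)
    meta_len[i] <- spec_i$length; meta_wid[i] <- spec_i$width; meta_ang[i] <- ang
    fld <- render_scene(scene_placement(
      list(list(spec = spec_i, position = c(0, 0, 0))), config))
    spec <- subtract_background(field_to_spectrum(fld))
    spec$values <- spec$values * shift_phase
    planes <- lapply(zv, function(z) spectrum_to_field(spec, z))
    refs[[i]] <- field_volume(planes, zv)
  }
  training_set(refs, labels,
               meta = tibble::tibble(reference = seq_along(labels),
                                     label = labels, length_um = meta_len,
                                     width_um = meta_wid,
                                     orientation_deg = meta_ang))
}
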