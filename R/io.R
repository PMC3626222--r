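# File formats.  Complex fields travel as two-page TIFF (real, imaginary)
# with 32-bit integer samples plus a JSON sidecar holding the linear
# scale/offset of each page and the optical configuration (quantisation
# ~2.3e-10 of the value range); a JSON format carries full double
# precision for lossless round trips.  Configs are YAML or JSON; filter
# models, scenes and reports are JSON.

#' @keywords internal
config_to_list <- function(config) {
  list(wavelength_um = config$wavelength, pitch_um = config$pixel_pitch,
       nx = config$nx, ny = config$ny, na = config$numerical_aperture,
       medium_index = config$medium_index)
}

#' @keywords internal
config_from_list <- function(lst) {
  optical_config(
    wavelength = lst$wavelength_um %||% 0.633,
    pixel_pitch = lst$pitch_um,
    nx = lst$nx, ny = lst$ny,
    numerical_aperture = lst$na %||% 1.25,
    medium_index = lst$medium_index %||% 1.33
  )
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an optical configuration from YAML or JSON
#'
#' Keys: `wavelength_um` (default 0.633), `pitch_um`, `nx`, `ny`, `na`
#' (default 1.25), `medium_index` (default 1.33).
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return An [optical_config()].
#' @export
read_optical_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  config_from_list(lst)
}

#' Write an optical configuration to YAML or JSON
#'
#' @param config An [optical_config()].
#' @param path Target path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_optical_config <- function(config, path) {
  lst <- config_to_list(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# map a real matrix to [0,1] for integer TIFF storage
#' @keywords internal
quantize_page <- function(m) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  list(page = (m - lo) / scale, offset = lo, scale = scale)
}

#' Write a complex field as a two-page TIFF
#'
#' Page 1 holds the real part, page 2 the imaginary part, stored as 32-bit
#' integer samples linearly mapped to `[0, 1]`; the mapping, the axial
#' position and the optical configuration go into a JSON sidecar at
#' `<path>.json`.  Round trip is exact to the 32-bit quantisation step
#' (~2.3e-10 of each page's value range).
#'
#' @param field A [complex_field()].
#' @param path Target `.tif` path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  re <- quantize_page(Re(field$values))
  im <- quantize_page(Im(field$values))
  tiff::writeTIFF(list(re$page, im$page), path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(kind = "complex_field", z_um = field$z,
         pages = list(
           real = list(offset = re$offset, scale = re$scale),
           imag = list(offset = im$offset, scale = im$scale)),
         config = config_to_list(field$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a complex field written by [write_field_tiff()]
#'
#' @param path The `.tif` path (its `.json` sidecar must sit next to it).
#' @return A [complex_field()].
#' @export
read_field_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  re <- pages[[1]] * meta$pages$real$scale + meta$pages$real$offset
  im <- pages[[2]] * meta$pages$imag$scale + meta$pages$imag$offset
  complex_field(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)),
                config_from_list(meta$config), z = meta$z_um)
}

#' Write an interferogram as a single-page TIFF
#'
#' Same quantised storage and sidecar scheme as [write_field_tiff()].
#'
#' @param interferogram Real matrix.
#' @param config The recording's [optical_config()].
#' @param path Target `.tif` path.
#' @param carrier Optional carrier `c(fx, fy)` recorded into the sidecar.
#' @return `path`, invisibly.
#' @export
write_interferogram_tiff <- function(interferogram, config, path, carrier = NULL) {
  q <- quantize_page(interferogram)
  tiff::writeTIFF(q$page, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(kind = "interferogram", offset = q$offset, scale = q$scale,
         carrier = carrier, config = config_to_list(config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an interferogram written by [write_interferogram_tiff()]
#'
#' @param path The `.tif` path.
#' @return List with `interferogram` (matrix), `config`, `carrier`.
#' @export
read_interferogram_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  page <- tiff::readTIFF(path)
  list(interferogram = page * meta$scale + meta$offset,
       config = config_from_list(meta$config),
       carrier = meta$carrier)
}

#' @keywords internal
complex_to_json <- function(m) list(re = Re(m), im = Im(m), dim = dim(m))

# robust to both simplified and nested list forms jsonlite may return
#' @keywords internal
complex_from_json <- function(lst) {
  d <- as.integer(unlist(lst$dim))
  re <- lst$re; im <- lst$im
  if (is.list(re)) re <- do.call(rbind, lapply(re, unlist))
  if (is.list(im)) im <- do.call(rbind, lapply(im, unlist))
  matrix(complex(real = as.numeric(re), imaginary = as.numeric(im)),
         nrow = d[1], ncol = d[2])
}

#' Write a complex field as JSON at full double precision
#'
#' Values survive the round trip through [read_field_json()] to within
#' the decimal-representation limit (~1e-15 relative).
#'
#' @param field A [complex_field()].
#' @param path Target `.json` path.
#' @return `path`, invisibly.
#' @export
write_field_json <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  jsonlite::write_json(
    list(kind = "complex_field", z_um = field$z,
         values = complex_to_json(field$values),
         config = config_to_list(field$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a complex field written by [write_field_json()]
#'
#' @param path The `.json` path.
#' @return A [complex_field()].
#' @export
read_field_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  complex_field(complex_from_json(lst$values),
                config_from_list(lst$config), z = lst$z_um)
}

#' Serialize a filter model to JSON
#'
#' Stores, per layer, the full-grid kernel (real/imaginary) and the four
#' threshold coefficients, plus the kernel extent and the optical
#' configuration, under a versioned schema.
#'
#' @param model A [filter_model()].
#' @param path Target `.json` path.
#' @return `path`, invisibly.
#' @export
write_filter_model <- function(model, path) {
  stopifnot(inherits(model, "filter_model"))
  layers <- lapply(seq_along(model$kernels), function(l) {
    cc <- model$thresholds[[l]]
    list(kernel = complex_to_json(model$kernels[[l]]$values),
         coeffs = list(re = Re(c(cc$a, cc$b, cc$c, cc$d)),
                       im = Im(c(cc$a, cc$b, cc$c, cc$d))))
  })
  jsonlite::write_json(
    list(kind = "filter_model", schema_version = 1L,
         kernel_extent = model$kernel_extent,
         config = config_to_list(model$config), layers = layers),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a filter model written by [write_filter_model()]
#'
#' @param path The `.json` path.
#' @return A [filter_model()].
#' @export
read_filter_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(lst$kind, "filter_model"))
  cfg <- config_from_list(lst$config)
  kernels <- list(); thresholds <- list()
  for (l in seq_along(lst$layers)) {
    lay <- lst$layers[[l]]
    kernels[[l]] <- spectral_kernel(complex_from_json(lay$kernel), cfg)
    cc <- complex(real = unlist(lay$coeffs$re), imaginary = unlist(lay$coeffs$im))
    thresholds[[l]] <- threshold_coeffs(cc[1], cc[2], cc[3], cc[4])
  }
  filter_model(kernels, thresholds,
               kernel_extent = as.integer(unlist(lst$kernel_extent)))
}

#' Write a scene description to JSON
#'
#' One record per rod: class, size, transmittance, position, orientation;
#' plus the optical configuration.
#'
#' @param scene A [scene_placement()].
#' @param path Target `.json` path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "scene_placement"))
  rods <- lapply(scene$rods, function(r) {
    list(class_label = r$spec$class_label, length_um = r$spec$length,
         width_um = r$spec$width, orientation_deg = r$spec$orientation,
         amplitude_transmittance = r$spec$amplitude_transmittance,
         phase_shift_rad = r$spec$phase_shift,
         x_um = r$position[1], y_um = r$position[2], z_um = r$position[3])
  })
  jsonlite::write_json(list(kind = "scene", rods = rods,
                            config = config_to_list(scene$config)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene description written by [write_scene()]
#'
#' @param path The `.json` path.
#' @return A [scene_placement()].
#' @export
read_scene <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- config_from_list(lst$config)
  rods <- lapply(lst$rods, function(r) {
    list(spec = rod_spec(r$class_label, length = r$length_um,
                         width = r$width_um, orientation = r$orientation_deg,
                         amplitude_transmittance = r$amplitude_transmittance,
                         phase_shift = r$phase_shift_rad),
         position = c(r$x_um, r$y_um, r$z_um))
  })
  scene_placement(rods, cfg)
}

#' Write a detection report as JSON and TSV
#'
#' @param report A `detection_report` from [find_peaks()].
#' @param path_stem Path without extension; `<stem>.json` and
#'   `<stem>.tsv` are written.
#' @return The JSON path, invisibly.
#' @export
write_detection_report <- function(report, path_stem) {
  stopifnot(inherits(report, "detection_report"))
  jsonlite::write_json(
    list(kind = "detection_report", threshold = report$threshold,
         min_separation = report$min_separation,
         config = config_to_list(report$config),
         detections = report$detections),
    paste0(path_stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    report$detections[, c("x_um", "y_um", "z_um", "score")],
    paste0(path_stem, ".tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paste0(path_stem, ".json"))
}

#' Write an annealing error trace as CSV
#'
#' Columns: step, temperature, current_E, best_E.
#'
#' @param trained A `trained_filter` from [anneal()].
#' @param path Target `.csv` path.
#' @return `path`, invisibly.
#' @export
write_anneal_trace <- function(trained, path) {
  stopifnot(inherits(trained, "trained_filter"))
  utils::write.csv(trained$trace, path, row.names = FALSE)
  invisible(path)
}
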