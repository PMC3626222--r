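# End-to-end detection: maximum-intensity projection of the filter output
# volume, 3D peak finding with greedy separation pruning, and the pipeline
# from scene to detection report.

#' Maximum-intensity projection of an output volume
#'
#' Per-pixel maximum over z — the standard way to display where the
#' correlation peaks of a volumetric filter output sit laterally.
#'
#' @param output An [output_volume()] (or numeric 3D array).
#' @return Real matrix of the plane shape.
#' @export
project_output <- function(output) {
  v <- if (inherits(output, "output_volume")) output$values else output
  stopifnot(is.array(v), length(dim(v)) == 3L)
  if (dim(v)[3] == 0L) stop("empty output volume", call. = FALSE)
  apply(v, c(1, 2), max)
}

#' Find correlation peaks in a filter output volume
#'
#' Local maxima (26-neighbourhood; circular laterally, clamped axially)
#' above `threshold` are pruned greedily so that no two detections lie
#' within `min_separation` voxels (Euclidean): higher score wins, ties are
#' broken by ascending lexicographic voxel index.  Voxel indices are
#' converted to µm using the configuration.  Filters trained on
#' zero-lag-shifted references anchor their template at the array origin,
#' so their correlation peak lands on the object's own pixel: the default
#' `"centered"` mapping reports the object's field coordinates directly.
#'
#' @param output An [output_volume()].
#' @param threshold Positive detection threshold (intensity units).
#' @param min_separation Minimum separation between detections in voxels
#'   (> 0): either one number or `c(lateral, axial)`.  Correlation
#'   responses are much more elongated axially than laterally (depth of
#'   field), so an ellipsoidal exclusion zone with a larger axial radius
#'   suppresses defocus-ridge duplicates of one object without merging
#'   laterally distinct ones.
#' @param origin `"centered"` (default: voxel maps straight to field
#'   coordinates with the origin at the grid centre pixel) or `"zero_lag"`
#'   (adds the centre offset, for outputs whose peak sits at the lag
#'   relative to a centred template).
#' @return An object of class `detection_report`: a tibble
#'   `(x_um, y_um, z_um, score, ix, iy, iz)` sorted by descending score,
#'   with the threshold and parameters attached as attributes.
#' @export
find_peaks <- function(output, threshold, min_separation = 3,
                       origin = c("centered", "zero_lag")) {
  stopifnot(inherits(output, "output_volume"), threshold > 0,
            length(min_separation) %in% c(1L, 2L))
  if (any(min_separation <= 0)) {
    stop("min_separation must be positive", call. = FALSE)
  }
  sep_lat <- min_separation[1]
  sep_ax <- min_separation[length(min_separation)]
  origin <- match.arg(origin)
  v <- output$values
  ny <- dim(v)[1]; nx <- dim(v)[2]; nz <- dim(v)[3]

  is_max <- array(TRUE, dim(v))
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    shifted <- v[((seq_len(ny) - 1 + dy) %% ny) + 1,
                 ((seq_len(nx) - 1 + dx) %% nx) + 1, , drop = FALSE]
    if (dz != 0) {
      zi <- seq_len(nz) + dz
      pad <- zi < 1 | zi > nz
      zi[pad] <- 1L
      shifted <- shifted[, , zi, drop = FALSE]
      shifted[, , pad] <- -Inf  # clamped axial boundary
    }
    is_max <- is_max & (v > shifted | (v == shifted &
      slice_index(dim(v)) < shifted_index(dim(v), dy, dx, dz)))
  }
  cand <- which(is_max & v > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(new_detection_report(tibble::tibble(
      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
      score = numeric(0), ix = integer(0), iy = integer(0), iz = integer(0)),
      threshold, min_separation, output$config))
  }
  score <- v[cand]
  lin <- (cand[, 3] - 1) * ny * nx + (cand[, 2] - 1) * ny + cand[, 1]
  ord <- order(-score, lin)
  cand <- cand[ord, , drop = FALSE]; score <- score[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(keep)) {
      kept <- cand[keep, , drop = FALSE]
      d2 <- ((kept[, 1] - cand[i, 1])^2 + (kept[, 2] - cand[i, 2])^2) / sep_lat^2 +
        (kept[, 3] - cand[i, 3])^2 / sep_ax^2
      ok <- all(d2 >= 1)
    }
    keep[i] <- ok
  }
  cand <- cand[keep, , drop = FALSE]; score <- score[keep]

  cfg <- output$config
  pos <- voxel_to_um(cand[, 2], cand[, 1], cand[, 3], cfg, output$z_values, origin)
  new_detection_report(tibble::tibble(
    x_um = pos$x, y_um = pos$y, z_um = pos$z, score = score,
    ix = as.integer(cand[, 2]), iy = as.integer(cand[, 1]),
    iz = as.integer(cand[, 3])),
    threshold, min_separation, cfg)
}

# linear index helpers for deterministic plateau tie-breaking
#' @keywords internal
slice_index <- function(d) {
  array(seq_len(prod(d)), d)
}

#' @keywords internal
shifted_index <- function(d, dy, dx, dz) {
  idx <- slice_index(d)
  out <- idx[((seq_len(d[1]) - 1 + dy) %% d[1]) + 1,
             ((seq_len(d[2]) - 1 + dx) %% d[2]) + 1, , drop = FALSE]
  if (dz != 0) {
    zi <- seq_len(d[3]) + dz
    pad <- zi < 1 | zi > d[3]
    zi[pad] <- 1L
    out <- out[, , zi, drop = FALSE]
    out[, , pad] <- .Machine$integer.max
  }
  out
}

#' @keywords internal
voxel_to_um <- function(ix, iy, iz, config, z_values, origin) {
  cx <- floor(config$nx / 2) + 1L
  cy <- floor(config$ny / 2) + 1L
  if (origin == "zero_lag") {
    px <- ((ix - 1L + (cx - 1L)) %% config$nx) + 1L
    py <- ((iy - 1L + (cy - 1L)) %% config$ny) + 1L
  } else {
    px <- ix; py <- iy
  }
  list(x = unname((px - cx) * config$pixel_pitch),
       y = unname((py - cy) * config$pixel_pitch),
       z = unname(z_values[iz]))
}

#' @keywords internal
new_detection_report <- function(tbl, threshold, min_separation, config) {
  structure(list(detections = tbl, threshold = threshold,
                 min_separation = min_separation, config = config),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> %d detection(s) above %.4g\n",
              nrow(x$detections), x$threshold))
  if (nrow(x$detections)) print(x$detections)
  invisible(x)
}

#' Run the full detection pipeline on a synthetic scene
#'
#' Render (optionally record and demodulate an off-axis hologram) ->
#' suppress the undiffracted background -> reconstruct the volume ->
#' apply the nonlinear filter (transplanted to the scene grid if trained
#' on smaller volumes) -> find peaks.  Deterministic for a fixed
#' placement.
#'
#' @param scene A [scene_placement()].
#' @param model A [filter_model()] (any grid at the same pixel pitch).
#' @param z_values Axial reconstruction grid (µm), uniform spacing.
#' @param threshold Detection threshold (see [calibrate_threshold()]).
#' @param min_separation Peak separation in voxels, scalar or c(lateral, axial). Default c(6, 24): the axial radius spans the defocus ridge of one object, so each object yields one detection (two objects stacked at the same lateral position are reported once — a documented limitation).
#' @param carrier Optional off-axis carrier `c(fx, fy)`; when given the
#'   field goes through [simulate_hologram()] and
#'   [demodulate_hologram()] instead of being used directly.
#' @param reference_amplitude Reference amplitude of the hologram path.
#' @param out_dir Optional directory; when given, the rendered field, the
#'   output projection and the report (JSON + TSV) are written there.
#' @return An object of class `pipeline_result`: `report`
#'   (a [find_peaks()] detection report), `output` (the
#'   [output_volume()]), `field`, `volume` and the parameters used.
#' @export
run_pipeline <- function(scene, model, z_values, threshold,
                         min_separation = c(6, 24), carrier = NULL,
                         reference_amplitude = 1, out_dir = NULL) {
  stopifnot(inherits(scene, "scene_placement"), inherits(model, "filter_model"))
  cfg <- scene$config
  field <- render_scene(scene)
  if (!is.null(carrier)) {
    holo <- simulate_hologram(field, carrier, reference_amplitude)
    field <- demodulate_hologram(holo, carrier, cfg, reference_amplitude)
  }
  spec <- subtract_background(field_to_spectrum(field))
  planes <- lapply(z_values, function(z) spectrum_to_field(spec, z))
  volume <- field_volume(planes, z_values)
  model_s <- if (same_config(model$config, cfg)) model else
    resample_filter_model(model, cfg)
  output <- apply_filter(model_s, volume)
  report <- find_peaks(output, threshold, min_separation)
  res <- structure(list(report = report, output = output, field = field,
                        volume = volume, scene = scene,
                        params = list(threshold = threshold,
                                      min_separation = min_separation,
                                      z_values = z_values,
                                      carrier = carrier)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_field_tiff(field, file.path(out_dir, "field.tif"))
    tiff::writeTIFF(project_output(output) / max(project_output(output), 1e-300),
                    file.path(out_dir, "projection.tif"), bits.per.sample = 16L)
    write_detection_report(report, file.path(out_dir, "detections"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Calibrate a detection threshold from training statistics
#'
#' The geometric mean of the minimum in-class peak and the maximum
#' out-of-class output of a [evaluate_filter()] run: the midpoint (in log
#' scale) of the separation gap, usable whenever the discrimination ratio
#' exceeds 1.
#'
#' @param evaluation A `filter_evaluation` from [evaluate_filter()].
#' @return Positive scalar threshold.
#' @export
calibrate_threshold <- function(evaluation) {
  stopifnot(inherits(evaluation, "filter_evaluation"))
  s <- evaluation$stats
  p_min <- min(s$peak[s$label == "in"])
  m_max <- max(s$max_output[s$label == "out"], 0)
  if (m_max <= 0) return(p_min / 4)
  if (p_min <= m_max) {
    warning("classes not separated on the training set; threshold set at the out-of-class maximum",
            call. = FALSE)
    return(m_max)
  }
  sqrt(p_min * m_max)
}
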