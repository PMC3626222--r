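# Convenience protocol: build rotation-generated references, warm-start
# from the matched filter, anneal, optionally add a sharpening layer.

#' Train a two-class rod classifier end to end
#'
#' The standard training protocol: build a rotation-generated
#' [training_set()] of the two rod classes, warm-start a single
#' correlation layer from the in-class [matched_filter_kernel()], and
#' refine it by [anneal()] against the delta-function desired outputs.
#'
#' @param n_inclass,n_outclass Reference counts. Defaults 6 and 6 (the
#'   scaled protocol; use 25/17 for the full-size one).
#' @param volume_shape Integer `c(ny, nx, nz)`. Default `c(16, 16, 8)`.
#' @param rotations Orientation steps cycled through (45 degrees each).
#'   Default 4.
#' @param kernel_extent Trainable spectral support. Default `c(16, 16)`.
#' @param seed Integer seed for the annealer (and the reference builder).
#' @param schedule An [anneal_schedule()]; defaults to the auto-scaled
#'   schedule with this `seed`.
#' @param size_jitter Relative rod size jitter for the references.
#'   Default 0 (pure rotation-generated references).
#' @param config Optional [optical_config()] for the references.
#' @param ... Passed to [build_training_set()] / [rod_spec()].
#' @return An object of class `rod_classifier`: `trained`
#'   (the [anneal()] result), `model`, `training_set`, `matched` (the
#'   warm-start kernel) and `evaluation` (an [evaluate_filter()] result
#'   for the trained model).
#' @export
train_rod_classifier <- function(n_inclass = 6L, n_outclass = 6L,
                                 volume_shape = c(16L, 16L, 8L),
                                 rotations = 4L, kernel_extent = c(16L, 16L),
                                 seed = 1L, schedule = NULL,
                                 size_jitter = 0, config = NULL, ...) {
  if (is.null(schedule)) schedule <- anneal_schedule(seed = seed)
  ts <- build_training_set(n_inclass, n_outclass, volume_shape = volume_shape,
                           rotations = rotations, rng_seed = seed,
                           config = config, size_jitter = size_jitter, ...)
  mf <- matched_filter_kernel(ts, kernel_extent)
  model0 <- filter_model(list(mf), kernel_extent = kernel_extent)
  trained <- anneal(model0, ts, schedule, optimize = "kernels")
  structure(list(trained = trained, model = trained$model,
                 training_set = ts, matched = mf,
                 evaluation = evaluate_filter(trained$model, ts)),
            class = "rod_classifier")
}

#' @export
print.rod_classifier <- function(x, ...) {
  cat("<rod_classifier>\n")
  print(x$trained)
  cat(sprintf("  discrimination ratio: %.4g\n", x$evaluation$discrimination_ratio))
  invisible(x)
}

#' Extend a trained filter with a sharpening layer
#'
#' Appends a second correlation layer with a delta (all-pass) kernel and a
#' pure-cubic threshold `T(x) = x^3`: the decision nonlinearity of the
#' cascade.  Cubing the complex values cubes every output intensity, so
#' the gap between in-class peaks and out-of-class responses — which a
#' single linear correlation cannot widen further — is raised to the third
#' power, at no cost to shift invariance.  Alternatively the new layer's
#' threshold coefficients can be annealed on the training set.
#'
#' @param classifier A `rod_classifier` from [train_rod_classifier()] (or
#'   a list with `model` and `training_set`).
#' @param coeffs [threshold_coeffs()] for the new layer. Default the pure
#'   cubic `a = 1`.
#' @param anneal_thresholds If `TRUE`, anneal the new layer's coefficients
#'   (starting from `coeffs`) instead of fixing them.
#' @param schedule An [anneal_schedule()] used when annealing; defaults to
#'   a short auto-scaled schedule seeded from the original.
#' @return The classifier with `model` (now two layers) and `evaluation`
#'   updated (plus `trained2` when annealed).
#' @export
add_sharpening_layer <- function(classifier,
                                 coeffs = threshold_coeffs(a = 1, c = 0),
                                 anneal_thresholds = FALSE,
                                 schedule = NULL) {
  model <- classifier$model
  ts <- classifier$training_set
  stopifnot(inherits(model, "filter_model"), inherits(ts, "training_set"))
  cfg <- model$config
  delta <- spectral_kernel(matrix(1 + 0i, cfg$ny, cfg$nx), cfg)
  model2 <- filter_model(c(model$kernels, list(delta)),
                         c(model$thresholds, list(coeffs)),
                         model$kernel_extent)
  if (anneal_thresholds) {
    if (is.null(schedule)) {
      seed0 <- if (inherits(classifier$trained, "trained_filter"))
        classifier$trained$schedule$seed else 1L
      schedule <- anneal_schedule(steps_per_temperature = 40L, seed = seed0 + 1L)
    }
    trained2 <- anneal(model2, ts, schedule, optimize = "thresholds", layers = 2L)
    classifier$trained2 <- trained2
    model2 <- trained2$model
  }
  classifier$model <- model2
  classifier$evaluation <- evaluate_filter(model2, ts)
  classifier
}
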