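# Filter training: delta-function desired outputs, the peak-weighted
# squared-error objective, and simulated annealing over the compact kernel
# supports and threshold coefficients.

#' A labelled set of reference volumes
#'
#' @param references List of [field_volume()] reference reconstructions.
#' @param labels Character vector, `"in"` (to be recognised) or `"out"`
#'   (to be rejected), one per reference.
#' @param desired Optional list of desired output arrays; built with
#'   [desired_output_for()] when omitted.
#' @param meta Optional tibble of per-reference metadata (rod geometry,
#'   orientation, ...).
#' @return An object of class `training_set`.
#' @export
training_set <- function(references, labels, desired = NULL, meta = NULL) {
  stopifnot(is.list(references), length(references) >= 1L,
            length(labels) == length(references),
            all(labels %in% c("in", "out")))
  for (r in references) stopifnot(inherits(r, "field_volume"))
  config <- references[[1]]$config
  for (r in references) stop_config_mismatch(r$config, config, "references")
  shape <- c(config$ny, config$nx, length(references[[1]]$z_values))
  if (is.null(desired)) {
    desired <- lapply(labels, desired_output_for, shape = shape)
  }
  stopifnot(length(desired) == length(references))
  for (d in desired) stopifnot(all(dim(d) == shape))
  structure(list(references = references, labels = labels, desired = desired,
                 config = config, shape = shape, meta = meta),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d references (%d in-class, %d out-of-class), volumes %d x %d x %d\n",
              length(x$references), sum(x$labels == "in"), sum(x$labels == "out"),
              x$shape[1], x$shape[2], x$shape[3]))
  invisible(x)
}

#' Desired filter output for a class label
#'
#' An in-class reference should produce a delta: zero everywhere except a
#' unit value at the first lexicographic element (the zero-lag voxel of the
#' first plane).  An out-of-class reference should produce zero everywhere.
#'
#' @param label `"in"` or `"out"`.
#' @param shape Integer `c(ny, nx, nz)`.
#' @return Numeric array of that shape.
#' @export
desired_output_for <- function(label, shape) {
  stopifnot(label %in% c("in", "out"), length(shape) == 3L, all(shape >= 1))
  o <- array(0, dim = shape)
  if (label == "in") o[1, 1, 1] <- 1
  o
}

#' Peak-weighted squared-error training objective
#'
#' `E = sum_ij (R_ij - O_ij)^2 + n sum_j (R_1j - O_1j)^2` over the `m`
#' reference outputs, where `n` is the number of voxels per volume and the
#' subscript 1 is the designated peak element (the first lexicographic
#' voxel).  The first term penalises deviation everywhere; the second gives
#' the peaks weight `n` so they reach their unit target.
#'
#' @param R List of output arrays (or [output_volume()]s).
#' @param O List of desired arrays of the same shapes.
#' @return Nonnegative scalar.
#' @export
objective <- function(R, O) {
  stopifnot(is.list(R), is.list(O), length(R) == length(O), length(R) >= 1L)
  E <- 0
  for (j in seq_along(R)) {
    r <- if (inherits(R[[j]], "output_volume")) R[[j]]$values else R[[j]]
    o <- O[[j]]
    if (!all(dim(r) == dim(o))) stop("output/desired shape mismatch", call. = FALSE)
    E <- E + sum((r - o)^2) + length(r) * (r[1] - o[1])^2
  }
  E
}

#' Simulated-annealing schedule
#'
#' Plumbing for [anneal()]: a geometric cooling schedule with a Metropolis
#' acceptance rule.  Temperatures are in objective units; leave them `NA`
#' to have [anneal()] scale them from the initial objective value
#' (`0.1 E0` down to `1e-4 E0`).
#'
#' @param t_initial,t_final Positive temperatures (`t_final <= t_initial`),
#'   or `NA` for automatic scaling.
#' @param cooling_factor Geometric factor in (0, 1). Default 0.95.
#' @param steps_per_temperature Moves per temperature (>= 0). Default 200.
#' @param step_scale Proposal scale relative to the parameter-group RMS at
#'   the initial temperature. Default 0.1, a fine-tuning scale suited to
#'   the matched-filter warm start (order-of-RMS moves throw the state far
#'   from it before cooling).
#' @param seed Integer RNG seed. Default 1.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_initial = NA, t_final = NA,
                            cooling_factor = 0.95,
                            steps_per_temperature = 200L,
                            step_scale = 0.1, seed = 1L) {
  if (!is.na(t_initial) && !is.na(t_final)) {
    stopifnot(t_initial > 0, t_final > 0, t_final <= t_initial)
  }
  stopifnot(cooling_factor > 0, cooling_factor < 1,
            steps_per_temperature >= 0, step_scale > 0)
  structure(list(t_initial = t_initial, t_final = t_final,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 step_scale = step_scale, seed = as.integer(seed)),
            class = "anneal_schedule")
}

# ---- fast cascade evaluation ------------------------------------------------

# Precompute, per reference, the propagated spectra P[,,m] = U exp(j2pi z_m kz)
# so that a layer-1 output plane is one elementwise product + inverse FFT.
#' @keywords internal
precompute_training_inputs <- function(ts) {
  cfg <- ts$config
  g <- kz_grid(cfg)
  zv <- ts$references[[1]]$z_values
  phases <- lapply(zv, function(z) exp(2i * pi * z * g$kz))
  lapply(ts$references, function(ref) {
    U <- field_to_spectrum(ref$planes[[1]])$values
    P <- array(0 + 0i, dim = c(cfg$ny, cfg$nx, length(zv)))
    for (m in seq_along(zv)) P[, , m] <- U * phases[[m]]
    P
  })
}

# Evaluate the full cascade for one precomputed reference.  `kernels` is a
# list of full-grid kernel value matrices, `thr` a list of threshold_coeffs.
# Later layers correlate each plane with the same z-independent kernel
# (see apply_correlation_op).
#' @keywords internal
cascade_output <- function(P, kernels, thr, cfg, zv) {
  nz <- dim(P)[3]
  n2 <- cfg$nx * cfg$ny
  rt <- sqrt(n2)
  x <- array(0 + 0i, dim = dim(P))
  K1 <- Conj(kernels[[1]])
  for (m in seq_len(nz)) x[, , m] <- ifft2_raw(P[, , m] * K1) / rt
  t1 <- thr[[1]]
  x <- t1$a * x^3 + t1$b * x^2 + t1$c * x + t1$d
  if (length(kernels) > 1) {
    for (l in 2:length(kernels)) {
      Kl <- Conj(kernels[[l]])
      for (m in seq_len(nz)) {
        x[, , m] <- ifft2_raw(stats::fft(x[, , m]) / rt * Kl) / rt
      }
      tl <- thr[[l]]
      x <- tl$a * x^3 + tl$b * x^2 + tl$c * x + tl$d
    }
  }
  Mod(x)^2
}

# Objective of a parameterised cascade over all references.
#' @keywords internal
cascade_objective <- function(Ps, O, kernels, thr, cfg, zv) {
  E <- 0
  for (j in seq_along(Ps)) {
    r <- cascade_output(Ps[[j]], kernels, thr, cfg, zv)
    o <- O[[j]]
    E <- E + sum((r - o)^2) + length(r) * (r[1] - o[1])^2
  }
  E
}

#' Matched-filter kernel of the in-class references
#'
#' The conjugate of the average in-class shell spectrum, restricted to the
#' trainable support and scaled so the mean in-class designated-peak
#' amplitude is 1.  This is the analytic linear baseline the annealer is
#' warm-started from (and measured against in tests).
#'
#' @param ts A [training_set()].
#' @param kernel_extent Integer `c(ky, kx)` trainable support.
#' @return A [spectral_kernel()] on the training grid.
#' @export
matched_filter_kernel <- function(ts, kernel_extent = c(16L, 16L)) {
  stopifnot(inherits(ts, "training_set"))
  cfg <- ts$config
  idx <- which(ts$labels == "in")
  stopifnot(length(idx) >= 1L)
  Uacc <- matrix(0 + 0i, cfg$ny, cfg$nx)
  for (j in idx) {
    Uacc <- Uacc + field_to_spectrum(ts$references[[j]]$planes[[1]])$values
  }
  # the correlation output is ifft(U . conj(H)), so the matched kernel is
  # the average spectrum itself (conjugation happens in the correlation)
  Uavg <- Uacc / length(idx)
  H <- pad_kernel(unpad_kernel(spectral_kernel(Uavg, cfg), kernel_extent), cfg)
  # scale: mean designated-peak amplitude over in-class refs -> 1
  peaks <- vapply(idx, function(j) {
    spec <- field_to_spectrum(ts$references[[j]]$planes[[1]])
    z1 <- ts$references[[j]]$z_values[1]
    Mod(correlate_plane(spec, H, z1)[1, 1])
  }, numeric(1))
  s <- mean(peaks)
  if (s <= 0) stop("degenerate in-class references: zero matched-filter peak", call. = FALSE)
  spectral_kernel(H$values / s, cfg)
}

# ---- the annealer -----------------------------------------------------------

#' Train a filter by simulated annealing
#'
#' Metropolis acceptance on the objective `E` under geometric cooling.
#' Each move perturbs one randomly chosen free parameter (a complex kernel
#' support entry or threshold coefficient) by a complex Gaussian whose
#' scale shrinks with temperature.  The best model ever visited is
#' returned; its best-so-far error trace is non-increasing by
#' construction, and the whole run is reproducible from the schedule seed.
#'
#' @param model0 Initial [filter_model()] (see [matched_filter_kernel()]
#'   for the recommended warm start).
#' @param ts A [training_set()] on the same grid.
#' @param schedule An [anneal_schedule()].
#' @param optimize Which parameter groups move: any of `"kernels"`,
#'   `"thresholds"`. Default kernels only.
#' @param layers Integer vector of layer indices to train; default all.
#' @return An object of class `trained_filter`: the best `model`, a
#'   `trace` tibble (step, temperature, current_E, best_E), initial and
#'   final objective values.
#' @export
anneal <- function(model0, ts, schedule = anneal_schedule(),
                   optimize = "kernels", layers = NULL) {
  stopifnot(inherits(model0, "filter_model"), inherits(ts, "training_set"),
            inherits(schedule, "anneal_schedule"),
            all(optimize %in% c("kernels", "thresholds")))
  stop_config_mismatch(model0$config, ts$config, "model and training set")
  if (length(ts$references) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(layers)) layers <- seq_along(model0$kernels)

  cfg <- model0$config
  zv <- ts$references[[1]]$z_values
  ext <- model0$kernel_extent
  Ps <- precompute_training_inputs(ts)
  O <- ts$desired

  # parameter table: one row per free complex scalar
  par <- list()
  for (l in layers) {
    if ("kernels" %in% optimize) {
      supp <- unpad_kernel(model0$kernels[[l]], ext)
      for (i in seq_len(ext[1])) for (j in seq_len(ext[2])) {
        par[[length(par) + 1L]] <- list(layer = l, kind = "kernel", i = i, j = j)
      }
    }
    if ("thresholds" %in% optimize) {
      for (nm in c("a", "b", "c", "d")) {
        par[[length(par) + 1L]] <- list(layer = l, kind = "coeff", name = nm)
      }
    }
  }
  if (length(par) == 0L) stop("nothing to optimize", call. = FALSE)

  # working state: kernel supports + coeffs per layer
  supports <- lapply(model0$kernels, unpad_kernel, extent = ext)
  coeffs <- model0$thresholds
  kernels_full <- lapply(model0$kernels, function(k) k$values)

  get_par <- function(p) {
    if (p$kind == "kernel") supports[[p$layer]][p$i, p$j] else coeffs[[p$layer]][[p$name]]
  }
  set_par <- function(p, v) {
    if (p$kind == "kernel") {
      supports[[p$layer]][p$i, p$j] <<- v
      kernels_full[[p$layer]] <<- pad_kernel(supports[[p$layer]], cfg)$values
    } else {
      coeffs[[p$layer]][[p$name]] <<- v
    }
  }

  # per-group proposal scales from the initial parameter RMS
  rms <- function(v) sqrt(mean(Mod(v)^2))
  scale_kernel <- max(rms(unlist(supports[layers])), 1e-6)
  scale_coeff <- max(rms(unlist(lapply(coeffs[layers], function(cc) {
    c(cc$a, cc$b, cc$c, cc$d)
  }))), 1e-6)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(schedule$seed)

  E_cur <- cascade_objective(Ps, O, kernels_full, coeffs, cfg, zv)
  E0 <- E_cur

  # auto temperature: probe moves at the initial proposal scale; T0 set so
  # a median uphill move is accepted with probability ~1/2 (acceptance-
  # ratio rule), cooling down four decades
  if (is.na(schedule$t_initial)) {
    n_probe <- min(30L, max(10L, length(par)))
    ups <- numeric(0)
    for (q in seq_len(n_probe)) {
      p <- par[[sample.int(length(par), 1L)]]
      sc <- (if (p$kind == "kernel") scale_kernel else scale_coeff) * schedule$step_scale
      old <- get_par(p)
      set_par(p, old + complex(real = stats::rnorm(1, 0, sc),
                               imaginary = stats::rnorm(1, 0, sc)))
      dE <- cascade_objective(Ps, O, kernels_full, coeffs, cfg, zv) - E_cur
      set_par(p, old)
      if (dE > 0) ups <- c(ups, dE)
    }
    t_init <- if (length(ups)) stats::median(ups) / log(2) else max(E0, 1e-12) * 1e-3
    t_fin <- if (is.na(schedule$t_final)) 1e-4 * t_init else schedule$t_final
  } else {
    t_init <- schedule$t_initial
    t_fin <- if (is.na(schedule$t_final)) 1e-4 * t_init else schedule$t_final
  }

  best_supports <- supports; best_coeffs <- coeffs; E_best <- E_cur
  n_temps <- if (t_fin >= t_init) 1L else
    1L + floor(log(t_fin / t_init) / log(schedule$cooling_factor) + 1e-9)
  n_total <- (n_temps + 2L) * schedule$steps_per_temperature
  trace_step <- integer(n_total)
  trace_T <- trace_cur <- trace_best <- numeric(n_total)

  temp <- t_init
  step <- 0L
  while (temp >= t_fin * (1 - 1e-12) && schedule$steps_per_temperature > 0L) {
    for (s in seq_len(schedule$steps_per_temperature)) {
      step <- step + 1L
      p <- par[[sample.int(length(par), 1L)]]
      sc <- (if (p$kind == "kernel") scale_kernel else scale_coeff) *
        schedule$step_scale * (temp / t_init)
      old <- get_par(p)
      set_par(p, old + complex(real = stats::rnorm(1, 0, sc),
                               imaginary = stats::rnorm(1, 0, sc)))
      E_new <- cascade_objective(Ps, O, kernels_full, coeffs, cfg, zv)
      dE <- E_new - E_cur
      if (dE <= 0 || stats::runif(1) < exp(-dE / temp)) {
        E_cur <- E_new
        if (E_cur < E_best) {
          E_best <- E_cur
          best_supports <- supports; best_coeffs <- coeffs
        }
      } else {
        set_par(p, old)
      }
      if (step <= n_total) {
        trace_step[step] <- step
        trace_T[step] <- temp
        trace_cur[step] <- E_cur
        trace_best[step] <- E_best
      }
    }
    temp <- temp * schedule$cooling_factor
  }
  keep <- seq_len(min(step, n_total))
  trace_step <- trace_step[keep]; trace_T <- trace_T[keep]
  trace_cur <- trace_cur[keep]; trace_best <- trace_best[keep]

  best_model <- filter_model(
    lapply(seq_along(best_supports), function(l) {
      if (l %in% layers && "kernels" %in% optimize) {
        pad_kernel(best_supports[[l]], cfg)
      } else {
        model0$kernels[[l]]
      }
    }),
    best_coeffs, ext
  )
  structure(list(
    model = best_model,
    trace = tibble::tibble(step = trace_step, temperature = trace_T,
                           current_E = trace_cur, best_E = trace_best),
    initial_E = E0, final_E = E_best, schedule = schedule
  ), class = "trained_filter")
}

#' @export
print.trained_filter <- function(x, ...) {
  cat(sprintf("<trained_filter> E: %.6g -> %.6g over %d moves\n",
              x$initial_E, x$final_E, nrow(x$trace)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the annealing trace of a trained filter
#'
#' @param x A `trained_filter` from [anneal()].
#' @param ... Unused.
#' @return A tibble with columns step, temperature, current_E, best_E.
#' @export
tidy.trained_filter <- function(x, ...) x$trace

#' One-row summary of a training run
#'
#' @param x A `trained_filter` from [anneal()].
#' @param ... Unused.
#' @return A tibble with initial/final objective, move count and layer count.
#' @export
glance.trained_filter <- function(x, ...) {
  tibble::tibble(initial_E = x$initial_E, final_E = x$final_E,
                 n_moves = nrow(x$trace),
                 n_layers = length(x$model$kernels))
}

#' Peak and sidelobe statistics of a filter on a reference set
#'
#' Runs [apply_filter()] on every reference and reports the designated-peak
#' value (first lexicographic voxel), the maximum output anywhere in the
#' volume, and the discrimination ratio: minimum in-class peak divided by
#' maximum out-of-class output.  A ratio above 1 means one threshold
#' separates the classes; `Inf` is reported when every out-of-class output
#' is exactly zero.
#'
#' @param model A [filter_model()].
#' @param ts A [training_set()].
#' @return An object of class `filter_evaluation`: a `stats` tibble
#'   (reference, label, peak, max_output) plus `discrimination_ratio`.
#' @export
evaluate_filter <- function(model, ts) {
  stopifnot(inherits(model, "filter_model"), inherits(ts, "training_set"))
  n <- length(ts$references)
  peak <- max_out <- numeric(n)
  for (j in seq_len(n)) {
    out <- apply_filter(model, ts$references[[j]])$values
    peak[j] <- out[1, 1, 1]
    max_out[j] <- max(out)
  }
  stats <- tibble::tibble(reference = seq_len(n), label = ts$labels,
                          peak = peak, max_output = max_out)
  denom <- max(max_out[ts$labels == "out"], 0)
  ratio <- if (denom == 0) Inf else min(peak[ts$labels == "in"]) / denom
  structure(list(stats = stats, discrimination_ratio = ratio),
            class = "filter_evaluation")
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat(sprintf("<filter_evaluation> discrimination ratio %.4g\n",
              x$discrimination_ratio))
  print(x$stats)
  invisible(x)
}
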