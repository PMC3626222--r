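# ggplot2 displays for the main result types.

#' @keywords internal
matrix_to_df <- function(m, config = NULL) {
  ny <- nrow(m); nx <- ncol(m)
  p <- if (is.null(config)) 1 else config$pixel_pitch
  cx <- floor(nx / 2) + 1; cy <- floor(ny / 2) + 1
  data.frame(
    x = rep((seq_len(nx) - cx) * p, each = ny),
    y = rep((seq_len(ny) - cy) * p, times = nx),
    value = as.vector(m)
  )
}

#' Plot the amplitude or phase of a complex field
#'
#' @param field A [complex_field()].
#' @param what `"amplitude"` (default), `"intensity"` or `"phase"`.
#' @return A ggplot object (x/y in µm).
#' @export
plot_field <- function(field, what = c("amplitude", "intensity", "phase")) {
  stopifnot(inherits(field, "complex_field"))
  what <- match.arg(what)
  m <- switch(what,
              amplitude = Mod(field$values),
              intensity = Mod(field$values)^2,
              phase = Arg(field$values))
  df <- matrix_to_df(m, field$config)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("%s at z = %.3g µm", what, field$z))
}

#' Plot the maximum-intensity projection of an output volume
#'
#' @param output An [output_volume()].
#' @param report Optional `detection_report` overlaid as circles.
#' @return A ggplot object.
#' @export
plot_projection <- function(output, report = NULL) {
  stopifnot(inherits(output, "output_volume"))
  proj <- fftshift2(project_output(output))  # zero lag recentred for display
  df <- matrix_to_df(proj, output$config)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "max-z projection of the filter output")
  if (!is.null(report) && nrow(report$detections)) {
    p <- p + ggplot2::geom_point(
      data = as.data.frame(report$detections),
      ggplot2::aes(x = .data$x_um, y = .data$y_um),
      inherit.aes = FALSE, shape = 1, colour = "red", size = 4, stroke = 1)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot the annealing error trace
#'
#' @param object A `trained_filter` from [anneal()].
#' @param ... Unused.
#' @return A ggplot of current and best-so-far objective versus move.
#' @export
autoplot.trained_filter <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$current_E), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_E), colour = "black") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "move", y = "objective E",
                  title = "simulated annealing trace (grey: current, black: best)")
}

#' Autoplot a detection report
#'
#' @param object A `detection_report` from [find_peaks()].
#' @param ... Unused.
#' @return A ggplot of detection positions sized by score.
#' @export
autoplot.detection_report <- function(object, ...) {
  df <- as.data.frame(object$detections)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   size = .data$score)) +
    ggplot2::geom_point(shape = 1, colour = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", title = "detections")
}

#' @importFrom rlang .data
NULL
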