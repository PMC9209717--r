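#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

close_ring <- function(df) df[c(seq_len(nrow(df)), 1L), ]

#' @describeIn fit_ccps plot the seed points and the fitted closed
#'   principal curve (pixel space).
#' @export
autoplot.ccps_fit <- function(object, ...) {
  curve_pix <- denormalize_points(object$curve, object$norm_params)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_path(data = close_ring(curve_pix), colour = "firebrick") +
    ggplot2::geom_point(data = curve_pix, colour = "firebrick", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Closed principal curve", x = "x (px)", y = "y (px)")
}

#' @describeIn de_minimize plot the best-fitness history.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste0(object$config$variant, " convergence"),
                  x = "generation", y = "best fitness")
}

#' @describeIn train_abpnn plot the training-error and learning-rate
#'   traces.
#' @export
autoplot.abpnn_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("error", "eta"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = "Network training", x = "epoch", y = NULL)
}

#' @describeIn segment_contour plot seeds, curve vertices, and the final
#'   smooth contour; pass `truth` (a polyline) to overlay ground truth.
#' @param truth optional ground-truth polyline to overlay.
#' @export
autoplot.pcseg_segmentation <- function(object, truth = NULL, ...) {
  seeds <- object$ccps_fit$points
  verts <- tidy(object$ccps_fit)
  p <- ggplot2::ggplot(seeds, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_path(data = close_ring(object$contour),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_point(data = verts, colour = "steelblue", size = 2)
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_path(data = close_ring(as_polyline(truth)),
                                colour = "grey40", linetype = "dashed")
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = "Segmented contour", x = "x (px)", y = "y (px)")
}

#' @importFrom rlang .data
NULL
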