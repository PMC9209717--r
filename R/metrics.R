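#' Rasterize a closed polygon to a binary mask
#'
#' Pixel conventions used throughout the package: 0-based indices,
#' `x` = column, `y` = row, and pixel `(row, col)` has its center at
#' `(col + 0.5, row + 0.5)`.  A pixel is set when its center is inside
#' the polygon under the even-odd rule; points exactly on an edge follow
#' the half-open crossing convention, which keeps shared edges between
#' adjacent polygons unambiguous.
#'
#' @param polygon a closed polyline (tibble `x`, `y`, pixel units).
#' @param height,width frame dimensions in pixels.
#' @return an integer `height x width` matrix of 0/1 (row 1 = row 0 of
#'   the image).
#' @examples
#' sq <- as_polyline(data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)))
#' sum(rasterize_mask(sq, 20, 20))  # 100 pixels
#' @export
rasterize_mask <- function(polygon, height, width) {
  polygon <- as_polyline(polygon)
  stopifnot(height >= 1, width >= 1)
  px <- rep(seq_len(width) - 0.5, each = height)
  py <- rep(seq_len(height) - 0.5, times = width)
  inside <- rep(FALSE, height * width)
  n <- nrow(polygon)
  xs <- polygon$x; ys <- polygon$y
  j <- n
  for (i in seq_len(n)) {
    crosses <- (ys[i] > py) != (ys[j] > py)
    if (any(crosses)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
    j <- i
  }
  mask <- matrix(as.integer(inside), nrow = height, ncol = width)
  if (!any(mask == 1L)) {
    rlang::warn("polygon does not cover any pixel center; mask is empty",
      class = "pcseg_empty_mask")
  }
  mask
}

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth equal-shaped 0/1 matrices.
#' @return a tibble with columns `tp`, `fp`, `fn`, `tn` (summing to the
#'   frame size).
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    rlang::abort("mask shapes differ", class = "pcseg_shape_mismatch")
  }
  p <- pred == 1L
  t_ <- truth == 1L
  tibble::tibble(tp = sum(p & t_), fp = sum(p & !t_),
                 fn = sum(!p & t_), tn = sum(!p & !t_))
}

#' Overlap metrics from confusion counts
#'
#' Dice similarity `2TP / (2TP + FP + FN)`, Jaccard similarity
#' `TP / (TP + FP + FN)`, and pixel accuracy
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' @param counts a one-row tibble/list with `tp`, `fp`, `fn`, `tn`.
#' @return a fraction in `[0, 1]`.
#' @export
metric_dsc <- function(counts) {
  d <- 2 * counts$tp + counts$fp + counts$fn
  if (d == 0) rlang::abort("DSC undefined: TP + FP + FN = 0",
    class = "pcseg_undefined_metric")
  2 * counts$tp / d
}

#' @rdname metric_dsc
#' @export
metric_jaccard <- function(counts) {
  d <- counts$tp + counts$fp + counts$fn
  if (d == 0) rlang::abort("Jaccard undefined: TP + FP + FN = 0",
    class = "pcseg_undefined_metric")
  counts$tp / d
}

#' @rdname metric_dsc
#' @export
metric_accuracy <- function(counts) {
  (counts$tp + counts$tn) / (counts$tp + counts$fp + counts$fn + counts$tn)
}

#' @describeIn metric_dsc all three metrics for a mask pair, as a
#'   one-row tibble `dsc`, `jaccard`, `accuracy`.
#' @param pred,truth equal-shaped 0/1 matrices.
#' @export
mask_metrics <- function(pred, truth) {
  counts <- confusion_counts(pred, truth)
  tibble::tibble(dsc = metric_dsc(counts),
                 jaccard = metric_jaccard(counts),
                 accuracy = metric_accuracy(counts))
}

#' Curve-to-data distance
#'
#' Mean squared Euclidean distance from the seed points to the fitted
#' contour, measured in normalized coordinates (so values are
#' comparable across frames).  The distance is taken to the sampled
#' polyline (segments included), not just to the sample points.
#'
#' @param fn a `contour_fn`, or a polyline already in normalized
#'   coordinates.
#' @param points seed points in pixel coordinates (columns `x`, `y`)
#'   when `fn` is a `contour_fn`, otherwise already normalized.
#' @param samples number of contour samples (>= 32), default 360.
#' @param norm_params `zscore_params` used when `fn` is a plain
#'   polyline given in normalized space and `points` are pixels.
#' @return mean squared distance (>= 0).
#' @export
delta_f <- function(fn, points, samples = 360L, norm_params = NULL) {
  stopifnot(samples >= 32)
  if (inherits(fn, "contour_fn")) {
    np <- fn$scaler$norm_params
    pts_n <- normalize_points(points, np)
    contour_pix <- contour_evaluate(fn, (seq_len(samples) - 1) / samples)
    poly_n <- normalize_points(contour_pix, np)
  } else {
    poly_n <- as_polyline(fn)
    pts_n <- if (is.null(norm_params)) tibble::as_tibble(points)
             else normalize_points(points, norm_params)
  }
  mean(dist2_to_polyline(pts_n, as_polyline(poly_n)))
}
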