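#' Segment a closed contour from seed points
#'
#' The full two-stage pipeline: a constrained closed polygonal principal
#' curve is fitted to the seed points, its ordered vertex sequence
#' trains the evolution-initialized network, and the trained network is
#' sampled into a smooth closed contour in pixel space.
#'
#' @param seeds data frame of seed points, columns `x`, `y` (pixels).
#' @param ccps a [ccps_config()].
#' @param abpnn an [abpnn_config()]; its `seed` is overridden by `seed`
#'   when that is given.
#' @param n_samples contour sampling resolution (default 360).
#' @param seed optional integer making the whole run bit-reproducible.
#' @return an object of class `pcseg_segmentation`: `ccps_fit`,
#'   `abpnn_fit`, `contour_fn`, `contour` (closed polyline tibble, pixel
#'   space), `delta_f_init` and `delta_f_final` (curve-to-data distance
#'   against the initial square and the final contour), `seed`.
#' @examples
#' \donttest{
#' fx <- make_fixture(shape_spec(), seed = 7)
#' seg <- segment_contour(fx$seeds, seed = 7)
#' glance(seg)
#' }
#' @export
segment_contour <- function(seeds, ccps = ccps_config(),
                            abpnn = abpnn_config(), n_samples = 360L,
                            seed = NULL) {
  if (!is.null(seed)) {
    abpnn$seed <- as.integer(seed)
    if (!is.null(abpnn$de_config)) abpnn$de_config$seed <- as.integer(seed)
  }
  cfit <- fit_ccps(seeds, ccps)
  afit <- train_abpnn(cfit$vertex_sequence, abpnn)
  fn <- contour_function(afit)
  contour <- sample_closed_contour(fn, n_samples)
  pts_n <- normalize_points(seeds, cfit$norm_params)
  d0 <- delta_f(init_square(), pts_n, samples = 360L)
  d1 <- delta_f(fn, seeds, samples = n_samples)
  structure(list(ccps_fit = cfit, abpnn_fit = afit, contour_fn = fn,
                 contour = contour, delta_f_init = d0, delta_f_final = d1,
                 seed = seed),
            class = "pcseg_segmentation")
}

#' @export
print.pcseg_segmentation <- function(x, ...) {
  cat("<pcseg_segmentation> ", nrow(x$ccps_fit$curve), " curve vertices -> ",
      nrow(x$contour), " contour points; delta_f ",
      signif(x$delta_f_init, 4), " -> ", signif(x$delta_f_final, 4), "\n",
      sep = "")
  invisible(x)
}

#' @rdname segment_contour
#' @param x,object a `pcseg_segmentation`.
#' @param ... unused.
#' @export
tidy.pcseg_segmentation <- function(x, ...) {
  ct <- x$contour
  tibble::tibble(x = ct$x, y = ct$y)
}

#' @rdname segment_contour
#' @export
glance.pcseg_segmentation <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$ccps_fit)[, c("n_points", "n_vertices", "stopped_by")],
    glance(x$abpnn_fit)[, c("q", "init_error", "final_error")],
    tibble::tibble(delta_f_init = x$delta_f_init,
                   delta_f_final = x$delta_f_final)
  )
}

#' Evaluate a segmentation against a ground-truth mask
#'
#' Rasterizes the predicted contour on the truth frame and reports the
#' overlap metrics plus the curve-to-data distance.
#'
#' @param seg a `pcseg_segmentation` (or a closed polyline in pixels).
#' @param truth_mask 0/1 matrix ground truth.
#' @param seeds seed points for the `delta_f` column (taken from `seg`
#'   when it is a segmentation).
#' @return a one-row tibble `dsc`, `jaccard`, `accuracy`, `delta_f`.
#' @export
evaluate_segmentation <- function(seg, truth_mask, seeds = NULL) {
  if (inherits(seg, "pcseg_segmentation")) {
    contour <- seg$contour
    df <- seg$delta_f_final
  } else {
    contour <- as_polyline(seg)
    df <- if (!is.null(seeds)) {
      nz <- zscore_normalize(seeds)
      delta_f(normalize_points(contour, nz$params), nz$points)
    } else NA_real_
  }
  pred <- rasterize_mask(contour, nrow(truth_mask), ncol(truth_mask))
  dplyr::bind_cols(mask_metrics(pred, truth_mask),
                   tibble::tibble(delta_f = df))
}
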