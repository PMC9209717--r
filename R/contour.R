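#' Coordinate scaler between normalized space and the network's range
#'
#' The network outputs, after the output map, live in (0, 1).  Training
#' targets are therefore min-max scaled per axis into
#' `[margin, 1 - margin]` so they are attainable, and the scaler also
#' carries the Z-score parameters needed to reach pixel space.
#'
#' @param seq a vertex sequence (tibble `t`, `x`, `y`, normalized
#'   coordinates) whose per-axis range defines the map.  The Z-score
#'   parameters are taken from its `"norm_params"` attribute unless
#'   given explicitly.
#' @param margin fraction of (0, 1) reserved at each end (default 0.1).
#' @param norm_params optional `zscore_params` override.
#' @return a list of class `contour_scaler`.
#' @export
contour_scaler <- function(seq, margin = 0.1, norm_params = NULL) {
  stopifnot(margin > 0, margin < 0.5)
  if (is.null(norm_params)) norm_params <- attr(seq, "norm_params")
  mins <- c(x = min(seq$x), y = min(seq$y))
  maxs <- c(x = max(seq$x), y = max(seq$y))
  if (any(maxs <= mins)) {
    rlang::abort("degenerate vertex sequence: zero coordinate range",
      class = "pcseg_degenerate_range")
  }
  structure(list(min = mins, max = maxs, margin = margin,
                 norm_params = norm_params),
            class = "contour_scaler")
}

#' @describeIn contour_scaler map normalized coordinates into
#'   `[margin, 1 - margin]^2`; returns a tibble `x`, `y`.
#' @param coords data frame with columns `x`, `y`.
#' @param scaler a `contour_scaler`.
#' @export
scale_coords <- function(coords, scaler) {
  sc <- function(v, axis) {
    scaler$margin + (1 - 2 * scaler$margin) *
      (v - scaler$min[[axis]]) / (scaler$max[[axis]] - scaler$min[[axis]])
  }
  tibble::tibble(x = sc(coords$x, "x"), y = sc(coords$y, "y"))
}

#' @describeIn contour_scaler inverse of [scale_coords()].
#' @export
unscale_coords <- function(coords, scaler) {
  un <- function(v, axis) {
    scaler$min[[axis]] + (v - scaler$margin) / (1 - 2 * scaler$margin) *
      (scaler$max[[axis]] - scaler$min[[axis]])
  }
  tibble::tibble(x = un(coords$x, "x"), y = un(coords$y, "y"))
}

#' Output map from the tanh range to (0, 1)
#'
#' The published closed-form map `(g + 1 - (1 - g^2)) / (2 g)` has a
#' removable singularity at `g = 0`; it is algebraically identical to
#' `(1 + g) / 2`, which is what this function computes.  The literal
#' form is kept as [map_output_printed()] and serves as a test oracle.
#'
#' @param g numeric (vector or matrix) strictly inside (-1, 1).
#' @return values in (0, 1), same shape as `g`.
#' @export
map_output <- function(g) {
  if (any(abs(g) >= 1)) {
    rlang::abort("output map requires |g| < 1", class = "pcseg_domain_error")
  }
  (1 + g) / 2
}

# tanh() saturates to exactly +-1 in doubles for |u| > ~19; the map is
# still well defined there, so internal numeric paths skip the domain
# check that the exported op enforces.
.map_output_unchecked <- function(g) (1 + g) / 2

#' @rdname map_output
#' @export
map_output_printed <- function(g) {
  (g + 1 - (1 - g^2)) / (2 * g)
}

#' Closed-form parametric contour from a trained network
#'
#' Bundles the trained parameters with the coordinate scaler into an
#' evaluable contour function `f(t) = (x(t), y(t))` in pixel space.
#'
#' @param fit an `abpnn_fit`, or an [abpnn_params()] together with
#'   `scaler`.
#' @param scaler a [contour_scaler()] (taken from `fit` when omitted).
#' @return a list of class `contour_fn`.
#' @export
contour_function <- function(fit, scaler = NULL) {
  if (inherits(fit, "abpnn_fit")) {
    params <- fit$params
    if (is.null(scaler)) scaler <- fit$scaler
  } else {
    params <- fit
  }
  stopifnot(inherits(params, "abpnn_params"), inherits(scaler, "contour_scaler"))
  structure(list(params = params, scaler = scaler), class = "contour_fn")
}

#' @describeIn contour_function evaluate the contour at curve parameters
#'   `t` (vector in `[0, 1]`); returns a tibble `t`, `x`, `y` in pixels.
#' @param fn a `contour_fn`.
#' @param t numeric vector in `[0, 1]`.
#' @export
contour_evaluate <- function(fn, t) {
  g <- abpnn_forward(fn$params, t)
  mapped <- .map_output_unchecked(g)
  norm <- unscale_coords(tibble::tibble(x = mapped[, 1], y = mapped[, 2]),
                         fn$scaler)
  pix <- denormalize_points(norm, fn$scaler$norm_params)
  tibble::tibble(t = t, x = pix$x, y = pix$y)
}

#' @describeIn contour_function sample the contour at `N` equispaced
#'   parameters into a closed polyline (pixel space, counterclockwise,
#'   coincident consecutive samples dropped).
#' @param N number of samples (>= 8), default 360.
#' @export
sample_closed_contour <- function(fn, N = 360L) {
  stopifnot(N >= 8)
  pts <- contour_evaluate(fn, (seq_len(N) - 1) / N)
  poly <- .dedupe_consecutive(tibble::tibble(x = pts$x, y = pts$y))
  if (nrow(unique(poly)) < 3L) {
    rlang::abort("degenerate contour: fewer than 3 distinct points",
      class = "pcseg_degenerate_contour")
  }
  polyline_ccw(as_polyline(poly))
}

#' Render the fitted contour as a closed-form text expression
#'
#' Writes the full parametric expression `x(t)`, `y(t)` with every
#' network coefficient and scaling constant inlined at full precision.
#' The text is valid R: parsing and evaluating it at any `t` reproduces
#' [contour_evaluate()] to machine precision.
#'
#' @param params an [abpnn_params()] (or an `abpnn_fit`).
#' @param scaler a [contour_scaler()] (taken from the fit when omitted).
#' @return a character scalar of class `contour_expression` with two
#'   assignment lines, `x_t <- ...` and `y_t <- ...`, each a function of
#'   the variable `t`.
#' @export
expression_text <- function(params, scaler = NULL) {
  if (inherits(params, "abpnn_fit")) {
    if (is.null(scaler)) scaler <- params$scaler
    params <- params$params
  }
  stopifnot(inherits(params, "abpnn_params"), inherits(scaler, "contour_scaler"))
  num <- function(v) formatC(v, format = "g", digits = 17)
  hidden <- vapply(seq_len(params$q), function(i) {
    sprintf("1/(1 + exp(-(%s*t - %s)))", num(params$omega[i]), num(params$tau[i]))
  }, character(1))
  axis_expr <- function(k, axis) {
    terms <- paste(vapply(seq_len(params$q), function(i) {
      sprintf("%s*%s", num(params$A[i, k]), hidden[i])
    }, character(1)), collapse = " + ")
    g <- sprintf("tanh(%s - %s)", terms, num(params$b[k]))
    mapped <- sprintf("(1 + %s)/2", g)
    norm <- sprintf("(%s + (%s - %s)/%s*(%s - %s))",
                    num(scaler$min[[axis]]), mapped, num(scaler$margin),
                    num(1 - 2 * scaler$margin),
                    num(scaler$max[[axis]]), num(scaler$min[[axis]]))
    np <- scaler$norm_params
    sprintf("%s + %s*%s", num(np$mu[[axis]]), num(np$sigma[[axis]]), norm)
  }
  txt <- paste0("x_t <- ", axis_expr(1, "x"), "\n",
                "y_t <- ", axis_expr(2, "y"), "\n")
  structure(txt, class = c("contour_expression", "character"))
}

#' @export
print.contour_expression <- function(x, ...) {
  cat(x)
  invisible(x)
}

#' @describeIn expression_text parse an expression text and evaluate it
#'   at curve parameters `t`; returns a tibble `t`, `x`, `y`.
#' @param text a `contour_expression` (or the same text re-read from file).
#' @param t numeric vector of curve parameters.
#' @export
evaluate_expression_text <- function(text, t) {
  env <- new.env(parent = baseenv())
  env$t <- t
  eval(parse(text = text), envir = env)
  tibble::tibble(t = t, x = env$x_t, y = env$y_t)
}
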