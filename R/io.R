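#' Read and write seed points, contours, and masks
#'
#' Seed points travel as CSV with header `x,y` (pixel units, 0-based,
#' `x` = column, `y` = row) or as a JSON array of `[x, y]` pairs.
#' Contours are CSV `t,x,y` in pixel coordinates.  Masks are 8-bit
#' grayscale PNG with values 0/255.
#'
#' @param path file path; the format is chosen by extension (`.csv` or
#'   `.json` for points).
#' @return `read_seed_points()` returns a tibble `x`, `y`.
#' @export
read_seed_points <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("seed-point file not found: ", path),
      class = "pcseg_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    arr <- jsonlite::fromJSON(path)
    if (is.list(arr)) arr <- do.call(rbind, arr)
    if (!is.matrix(arr) || ncol(arr) != 2) {
      rlang::abort("JSON seed points must be an array of [x, y] pairs",
        class = "pcseg_io_error")
    }
    pts <- tibble::tibble(x = as.numeric(arr[, 1]), y = as.numeric(arr[, 2]))
  } else {
    pts <- .read_numeric_csv(path, c("x", "y"))
  }
  validate_pointset(pts, min_n = 1L)
}

.read_numeric_csv <- function(path, cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df))) {
    rlang::abort(paste0(path, ": expected columns ", paste(cols, collapse = ",")),
      class = "pcseg_io_error")
  }
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      rlang::abort(sprintf("%s: non-numeric value in column `%s`, line %d",
                           path, cl, bad + 1L),
        class = "pcseg_io_error")
    }
  }
  tibble::as_tibble(df[cols])
}

#' @rdname read_seed_points
#' @param points tibble with columns `x`, `y`.
#' @export
write_seed_points <- function(points, path) {
  readr::write_csv(tibble::as_tibble(points)[, c("x", "y")], path)
  invisible(path)
}

#' @rdname read_seed_points
#' @param contour tibble with columns `t`, `x`, `y` (or `x`, `y`; `t`
#'   is then filled with equispaced values).
#' @export
write_contour <- function(contour, path) {
  df <- tibble::as_tibble(contour)
  if (!"t" %in% names(df)) df$t <- (seq_len(nrow(df)) - 1) / nrow(df)
  readr::write_csv(df[, c("t", "x", "y")], path)
  invisible(path)
}

#' @rdname read_seed_points
#' @export
read_contour <- function(path) {
  .read_numeric_csv(path, c("t", "x", "y"))
}

#' @rdname read_seed_points
#' @param mask 0/1 integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname read_seed_points
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(img > 0.5), nrow = nrow(img))
}

#' Read an image frame
#'
#' Returns the pixel grid of a grayscale PNG frame; the pixels are used
#' only for framing and overlays, never by the fitting itself.  DICOM
#' input is not supported by this build and raises an error.
#'
#' @param path path to a PNG file.
#' @return list with `height`, `width`, `pixels` (numeric matrix in
#'   `[0, 1]`).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("image not found: ", path), class = "pcseg_io_error")
  }
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) {
    rlang::abort("DICOM input is not supported; convert the frame to PNG",
      class = "pcseg_unsupported_format")
  }
  img <- tryCatch(png::readPNG(path), error = function(e) {
    rlang::abort(paste0("unreadable image: ", path), class = "pcseg_io_error")
  })
  if (length(dim(img)) == 3L) img <- img[, , 1]
  list(height = nrow(img), width = ncol(img), pixels = img)
}

#' Save and load a trained contour model as JSON
#'
#' The flat JSON document carries the hidden-layer size, all network
#' weights and thresholds, the coordinate scaler, and the Z-score
#' parameters, which is everything needed to re-evaluate the contour.
#'
#' @param fit an `abpnn_fit` or `contour_fn`.
#' @param path output path.
#' @export
write_model_json <- function(fit, path) {
  fn <- if (inherits(fit, "contour_fn")) fit else contour_function(fit)
  p <- fn$params
  s <- fn$scaler
  obj <- list(q = p$q, omega = p$omega, tau = p$tau,
              A1 = p$A[, 1], A2 = p$A[, 2], b = p$b,
              scaler = list(min = as.list(s$min), max = as.list(s$max),
                            margin = s$margin,
                            mu = as.list(s$norm_params$mu),
                            sigma = as.list(s$norm_params$sigma)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @return `read_model_json()` returns a `contour_fn`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  params <- abpnn_params(omega = obj$omega, tau = obj$tau,
                         A = cbind(obj$A1, obj$A2), b = obj$b)
  np <- structure(list(mu = unlist(obj$scaler$mu),
                       sigma = unlist(obj$scaler$sigma)),
                  class = "zscore_params")
  scaler <- structure(list(min = unlist(obj$scaler$min),
                           max = unlist(obj$scaler$max),
                           margin = obj$scaler$margin,
                           norm_params = np),
                      class = "contour_scaler")
  contour_function(params, scaler)
}
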