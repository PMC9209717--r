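#' Specification of a synthetic star-shaped organ contour
#'
#' Ground truth shapes are radial-harmonic perturbations of a circle,
#' `r(theta) = r0 * (1 + sum_k eps_k * cos(k * theta + phi_k))` for
#' harmonics `k = 2..5`.  Keeping `sum |eps_k| <= 0.3` guarantees a
#' strictly positive radius, so the contour is star-shaped and simple.
#' This emulates the variety of smooth closed organ cross-sections
#' (e.g. prostate slices) without any imaging physics.
#'
#' @param center length-2 numeric, shape center in pixels.
#' @param r0 base radius in pixels (>= 20).
#' @param eps named or plain numeric of harmonic amplitudes for
#'   `k = 2..5` (missing entries are 0).
#' @param phases harmonic phases (radians), recycled to length 4.
#' @param height,width frame size in pixels.
#' @return a list of class `shape_spec`.
#' @export
shape_spec <- function(center = c(128, 128), r0 = 80,
                       eps = c(0.1, 0, 0, 0), phases = 0,
                       height = 256L, width = 256L) {
  eps <- rep_len(as.numeric(eps), 4)
  phases <- rep_len(as.numeric(phases), 4)
  if (sum(abs(eps)) > 0.3) {
    rlang::abort("sum of |harmonic amplitudes| must be <= 0.3",
      class = "pcseg_invalid_spec")
  }
  if (r0 < 20) {
    rlang::abort("base radius must be at least 20 px", class = "pcseg_invalid_spec")
  }
  rmax <- r0 * (1 + sum(abs(eps)))
  if (center[1] - rmax < 0 || center[1] + rmax > width ||
      center[2] - rmax < 0 || center[2] + rmax > height) {
    rlang::abort("contour does not fit in the frame", class = "pcseg_invalid_spec")
  }
  structure(list(center = center, r0 = r0, eps = eps, phases = phases,
                 height = as.integer(height), width = as.integer(width)),
            class = "shape_spec")
}

#' @describeIn shape_spec draw a random in-frame spec (uniform
#'   amplitudes summing below the simplicity bound); deterministic for a
#'   fixed `seed`.
#' @param seed integer seed.
#' @export
random_shape_spec <- function(seed, height = 256L, width = 256L) {
  withr::with_seed(seed, {
    r0 <- stats::runif(1, 60, 90)
    raw <- stats::runif(4, 0, 1) * c(1, 0.7, 0.5, 0.3)
    eps <- raw / sum(raw) * stats::runif(1, 0.05, 0.25)
    phases <- stats::runif(4, 0, 2 * pi)
    shape_spec(center = c(width / 2, height / 2) + stats::runif(2, -10, 10),
               r0 = r0, eps = eps, phases = phases,
               height = height, width = width)
  })
}

#' Dense ground-truth contour of a synthetic shape
#'
#' @param spec a [shape_spec()].
#' @param n_vertices polygon density (default 512).
#' @return a counterclockwise closed polyline (tibble `x`, `y`).
#' @export
make_truth_contour <- function(spec, n_vertices = 512L) {
  stopifnot(inherits(spec, "shape_spec"), n_vertices >= 16)
  theta <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  r <- spec$r0 * (1 + Reduce(`+`, lapply(1:4, function(j) {
    spec$eps[j] * cos((j + 1) * theta + spec$phases[j])
  })))
  if (any(r <= 0)) {
    rlang::abort("invalid spec: radius function is not strictly positive",
      class = "pcseg_invalid_spec")
  }
  as_polyline(tibble::tibble(x = spec$center[1] + r * cos(theta),
                             y = spec$center[2] + r * sin(theta)))
}

#' Radiologist-like seed points from a dense contour
#'
#' Uniformly subsamples `ceiling(fraction * V)` of the `V` contour
#' vertices and perturbs them.  Placement `"near"` adds isotropic
#' Gaussian jitter of `jitter_sigma` pixels (picks close to the true
#' boundary); `"offset"` pushes each point outward from the shape
#' centroid by `|N(0, 3 * jitter_sigma)|`, emulating picks biased into
#' the shadowed regions beyond the boundary.
#'
#' @param contour a dense closed polyline (the truth contour).
#' @param fraction fraction of contour vertices to keep, in (0, 0.5].
#' @param jitter_sigma jitter scale in pixels.
#' @param placement `"near"` or `"offset"`.
#' @param seed optional integer; fixed seed gives identical points.
#' @return a tibble of seed points (columns `x`, `y`).
#' @export
sample_seed_points <- function(contour, fraction = 0.08, jitter_sigma = 1,
                               placement = c("near", "offset"), seed = NULL) {
  placement <- match.arg(placement)
  if (fraction <= 0 || fraction > 0.5) {
    rlang::abort("seed fraction must lie in (0, 0.5]", class = "pcseg_invalid_spec")
  }
  contour <- as_polyline(contour)
  V <- nrow(contour)
  k <- ceiling(fraction * V)
  draw <- function() {
    idx <- floor((seq_len(k) - 1) * V / k) + 1L
    pts <- contour[idx, ]
    if (placement == "near") {
      pts$x <- pts$x + stats::rnorm(k, 0, jitter_sigma)
      pts$y <- pts$y + stats::rnorm(k, 0, jitter_sigma)
    } else {
      cx <- mean(contour$x); cy <- mean(contour$y)
      ux <- pts$x - cx; uy <- pts$y - cy
      len <- sqrt(ux^2 + uy^2)
      push <- abs(stats::rnorm(k, 0, 3 * jitter_sigma))
      pts$x <- pts$x + push * ux / len
      pts$y <- pts$y + push * uy / len
    }
    tibble::as_tibble(pts)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (nrow(out) < 8L) {
    rlang::abort("fewer than 8 seed points; increase the fraction",
      class = "pcseg_too_few_points")
  }
  out
}

#' @describeIn make_truth_contour ground-truth binary mask of the shape
#'   (delegates to [rasterize_mask()]).
#' @param contour a closed polyline.
#' @param height,width frame size.
#' @export
make_mask <- function(contour, height, width) {
  rasterize_mask(contour, height, width)
}

#' Bundled synthetic fixture: seeds, truth contour, truth mask
#'
#' @param spec a [shape_spec()].
#' @param fraction,jitter_sigma,placement,seed as in
#'   [sample_seed_points()].
#' @return a list of class `pcseg_fixture` with `seeds`, `contour`,
#'   `mask`, `spec`.
#' @examples
#' fx <- make_fixture(shape_spec(), seed = 7)
#' nrow(fx$seeds)
#' @export
make_fixture <- function(spec, fraction = 0.08, jitter_sigma = 1,
                         placement = "near", seed = NULL) {
  contour <- make_truth_contour(spec)
  seeds <- sample_seed_points(contour, fraction, jitter_sigma, placement, seed)
  structure(list(seeds = seeds, contour = contour,
                 mask = make_mask(contour, spec$height, spec$width),
                 spec = spec),
            class = "pcseg_fixture")
}
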