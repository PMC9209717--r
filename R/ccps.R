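#' Configuration for the constrained closed polygonal principal-curve fit
#'
#' @param beta_stop whole-loop stop constant: the fit terminates once the
#'   segment count exceeds `beta_stop * n^(1/3) * delta_n^(-1/2) * r`
#'   (`n` seed points, mean squared projection distance `delta_n`, data
#'   radius `r`).  Default 0.3.
#' @param delta_s maximum distance deviation: inner and outer loops stop
#'   when the decrease of the total squared projection distance between
#'   successive passes falls below this value (normalized coordinates).
#'   Default 0.002.
#' @param min_projected_points a vertex is filtered out when fewer than
#'   this many points project onto it and its two adjacent segments.
#'   Default 5.
#' @param max_segments safety cap on the number of polygon segments.
#' @return a list of class `ccps_config`.
#' @export
ccps_config <- function(beta_stop = 0.3, delta_s = 0.002,
                        min_projected_points = 5L, max_segments = 50L) {
  stopifnot(beta_stop > 0, delta_s > 0, min_projected_points >= 1,
            max_segments >= 4)
  structure(list(beta_stop = beta_stop, delta_s = delta_s,
                 min_projected_points = as.integer(min_projected_points),
                 max_segments = as.integer(max_segments)),
            class = "ccps_config")
}

#' Z-score normalization of a 2-D point set
#'
#' Centers each axis on its mean and scales by its population standard
#' deviation, so the normalized set has per-axis mean 0 and population SD
#' 1.  The returned parameters invert the map exactly via
#' [denormalize_points()].
#'
#' @param points data frame with numeric columns `x`, `y` (pixel units).
#' @return list with `points` (normalized tibble) and `params`
#'   (`zscore_params`: `mu`, `sigma`, each a named length-2 vector).
#' @examples
#' zscore_normalize(data.frame(x = c(0, 2, 0, 2), y = c(0, 0, 2, 2)))
#' @export
zscore_normalize <- function(points) {
  points <- validate_pointset(points)
  n <- nrow(points)
  mu <- c(x = mean(points$x), y = mean(points$y))
  # population (1/n) standard deviation, not the sample (1/(n-1)) one
  sigma <- c(x = sqrt(mean((points$x - mu[["x"]])^2)),
             y = sqrt(mean((points$y - mu[["y"]])^2)))
  if (any(sigma == 0)) {
    rlang::abort("degenerate point set: zero variance on one axis",
      class = "pcseg_degenerate_variance")
  }
  params <- structure(list(mu = mu, sigma = sigma), class = "zscore_params")
  out <- tibble::tibble(x = (points$x - mu[["x"]]) / sigma[["x"]],
                        y = (points$y - mu[["y"]]) / sigma[["y"]])
  list(points = out, params = params)
}

#' @describeIn zscore_normalize map normalized coordinates back to pixels.
#' @param params a `zscore_params` object.
#' @export
denormalize_points <- function(points, params) {
  stopifnot(inherits(params, "zscore_params"))
  tibble::tibble(x = params$mu[["x"]] + params$sigma[["x"]] * points$x,
                 y = params$mu[["y"]] + params$sigma[["y"]] * points$y)
}

#' @describeIn zscore_normalize apply an existing normalization to points.
#' @export
normalize_points <- function(points, params) {
  stopifnot(inherits(params, "zscore_params"))
  tibble::tibble(x = (points$x - params$mu[["x"]]) / params$sigma[["x"]],
                 y = (points$y - params$mu[["y"]]) / params$sigma[["y"]])
}

validate_pointset <- function(points, min_n = 8L) {
  if (!all(c("x", "y") %in% names(points))) {
    rlang::abort("seed points need columns `x` and `y`", class = "pcseg_invalid_points")
  }
  points <- tibble::as_tibble(points)[, c("x", "y")]
  if (nrow(points) < min_n) {
    rlang::abort(sprintf("need at least %d seed points, got %d", min_n, nrow(points)),
      class = "pcseg_too_few_points")
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    rlang::abort("seed points must be finite", class = "pcseg_invalid_points")
  }
  points
}

#' Radius of a point set
#'
#' The largest Euclidean distance from any point to the centroid of the
#' set, used both by the whole-loop stop rule and by vertex filtering.
#'
#' @param points data frame with columns `x`, `y`.
#' @export
data_radius <- function(points) {
  stopifnot(nrow(points) >= 1)
  cx <- mean(points$x); cy <- mean(points$y)
  sqrt(max((points$x - cx)^2 + (points$y - cy)^2))
}

#' Initial closed square for the principal-curve fit
#'
#' The fit starts, in normalized coordinates, from the small closed
#' square with vertices (0.1, 0.1), (-0.1, 0.1), (-0.1, -0.1),
#' (0.1, -0.1) centred on the origin (the normalized data centroid).
#'
#' @return a 4-vertex polyline tibble (counterclockwise).
#' @export
init_square <- function() {
  tibble::tibble(x = c(0.1, -0.1, -0.1, 0.1),
                 y = c(0.1, 0.1, -0.1, -0.1))
}

#' Project points onto a closed polyline
#'
#' Each point is assigned to its nearest element of the curve: a vertex
#' or the interior of a segment (Euclidean distance; ties break toward
#' the lower element index, vertices before segments).  Segment `i` joins
#' vertex `i` to vertex `i + 1`, the last segment being the implicit
#' closing edge.
#'
#' @param points normalized points (columns `x`, `y`).
#' @param curve polyline tibble.
#' @return list of class `ccps_projection`: `assignment` (tibble with
#'   per-point `element` ("vertex"/"segment"), `index`, `dist2`),
#'   `vertex_counts`, `segment_counts`, `delta_n` (mean squared
#'   projection distance), `total` (sum of squared distances).
#' @export
project_points <- function(points, curve) {
  curve <- as_polyline(curve)
  m <- nrow(curve)
  d <- .pl_dist2(points$x, points$y, curve)
  # tie-break: vertices first, then segments, lower index first
  all_d <- cbind(d$vertex, d$segment)
  best <- max.col(-all_d, ties.method = "first")
  is_vertex <- best <= m
  index <- ifelse(is_vertex, best, best - m)
  dist2 <- all_d[cbind(seq_along(best), best)]
  assignment <- tibble::tibble(
    element = ifelse(is_vertex, "vertex", "segment"),
    index = as.integer(index),
    dist2 = dist2
  )
  structure(list(
    assignment = assignment,
    vertex_counts = tabulate(index[is_vertex], nbins = m),
    segment_counts = tabulate(index[!is_vertex], nbins = m),
    delta_n = mean(dist2),
    total = sum(dist2),
    m = m,
    points = tibble::tibble(x = points$x, y = points$y)
  ), class = "ccps_projection")
}

# Points belonging to vertex i's neighborhood: the vertex itself plus its
# two adjacent segments (segment i-1 and segment i, cyclically).
.neighborhood_idx <- function(projection, i) {
  m <- projection$m
  prev_seg <- if (i == 1L) m else i - 1L
  a <- projection$assignment
  which((a$element == "vertex" & a$index == i) |
        (a$element == "segment" & (a$index == i | a$index == prev_seg)))
}

# Squared distances of a set of points to the two-segment path
# a -> v -> b (vertex v included); used as the local objective when
# repositioning vertex v.
.local_path_dist2 <- function(px, py, a, v, b) {
  seg_d2 <- function(p1, p2) {
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    len2 <- ex^2 + ey^2
    if (len2 == 0) return((px - p1[1])^2 + (py - p1[2])^2)
    u <- pmin(1, pmax(0, ((px - p1[1]) * ex + (py - p1[2]) * ey) / len2))
    (px - p1[1] - u * ex)^2 + (py - p1[2] - u * ey)^2
  }
  pmin(seg_d2(a, v), seg_d2(v, b))
}

#' Vertex-position optimization sweep for the closed principal curve
#'
#' Repeatedly sweeps over the vertices.  Each vertex is repositioned by
#' a deterministic local minimization of the squared distances of the
#' points projecting onto it and its two adjacent segments: a
#' closed-form centroid step, refined by a short Nelder-Mead descent on
#' the local objective, accepted only if the *total* squared projection
#' distance of the whole curve decreases.  Sweeping stops when the
#' decrease between successive sweeps falls below `delta_s`.  The curve
#' stays closed and never ends worse than it started.
#'
#' @inheritParams project_points
#' @param config a [ccps_config()].
#' @param max_sweeps safety bound on the number of sweeps.
#' @param r optional data radius; candidate positions are clamped into
#'   the disk of radius `r` about the data centroid so the optimizer
#'   honors the same constraint the vertex filter enforces.
#' @return the improved polyline.
#' @export
optimize_vertices <- function(curve, points, config = ccps_config(),
                              max_sweeps = 100L, r = Inf) {
  curve <- as_polyline(curve)
  cx <- mean(points$x); cy <- mean(points$y)
  clamp_r <- function(v) {
    d <- sqrt((v[1] - cx)^2 + (v[2] - cy)^2)
    if (d > r) c(cx, cy) + (v - c(cx, cy)) * (r / d) else v
  }
  total_cur <- project_points(points, curve)$total
  total_prev <- total_cur
  for (sweep in seq_len(max_sweeps)) {
    proj <- project_points(points, curve)
    for (i in seq_len(nrow(curve))) {
      idx <- .neighborhood_idx(proj, i)
      if (length(idx) == 0L) next
      m <- nrow(curve)
      prv <- if (i == 1L) m else i - 1L
      nxt <- if (i == m) 1L else i + 1L
      a <- c(curve$x[prv], curve$y[prv])
      b <- c(curve$x[nxt], curve$y[nxt])
      px <- points$x[idx]; py <- points$y[idx]
      local_obj <- function(v) sum(.local_path_dist2(px, py, a, v, b))
      centroid <- c(mean(px), mean(py))
      refined <- clamp_r(stats::optim(centroid, local_obj, method = "Nelder-Mead",
                                      control = list(maxit = 80))$par)
      cand_pos <- if (local_obj(refined) < local_obj(centroid)) refined else centroid
      for (pos in list(cand_pos, centroid)) {
        if (all(pos == a) || all(pos == b)) next
        cand <- curve
        cand$x[i] <- pos[1]; cand$y[i] <- pos[2]
        total_cand <- project_points(points, cand)$total
        if (total_cand < total_cur) {
          curve <- cand
          total_cur <- total_cand
          proj <- project_points(points, curve)
          break
        }
      }
    }
    if (abs(total_prev - total_cur) < config$delta_s) break
    total_prev <- total_cur
  }
  curve
}

#' Insert a vertex into the segment with the largest misfit
#'
#' The segment carrying the greatest total squared projection distance
#' (among segments with at least two projected points) is split by a new
#' vertex at the centroid of the points projecting onto it.
#'
#' @inheritParams optimize_vertices
#' @param projection the [project_points()] result for `curve`.
#' @return the polyline with exactly one vertex added.
#' @export
insert_vertex <- function(curve, projection) {
  curve <- as_polyline(curve)
  stopifnot(inherits(projection, "ccps_projection"), projection$m == nrow(curve))
  a <- projection$assignment
  seg_tot <- vapply(seq_len(projection$m), function(i) {
    sum(a$dist2[a$element == "segment" & a$index == i])
  }, numeric(1))
  eligible <- projection$segment_counts >= 2L
  if (!any(eligible)) {
    rlang::abort("no segment has at least two projected points to split",
      class = "pcseg_no_splittable_segment")
  }
  seg_tot[!eligible] <- -Inf
  i <- which.max(seg_tot)
  idx <- which(a$element == "segment" & a$index == i)
  # new vertex at the centroid of the points projecting onto segment i
  new_x <- mean(projection$points$x[idx])
  new_y <- mean(projection$points$y[idx])
  out <- tibble::add_row(curve, x = new_x, y = new_y, .after = i)
  as_polyline(out)
}

#' Remove abnormal vertices from the closed principal curve
#'
#' A vertex is flagged when it lies farther than the data radius `r`
#' from the data centroid, or when fewer than `min_projected_points`
#' points project onto it and its two adjacent segments.  A vertex
#' outside the radius is always removed; a merely starved vertex is
#' removed only when dropping it does not worsen the total squared
#' projection distance by more than `delta_s` (a vertex whose removal
#' degrades the fit is load-bearing, not abnormal).  Removal preserves
#' closure and never reduces the curve below 3 vertices; the removed
#' vertex positions are attached as the `"removed"` attribute.
#'
#' @inheritParams insert_vertex
#' @param r data radius from [data_radius()].
#' @param config a [ccps_config()].
#' @export
filter_vertices <- function(curve, projection, r, config = ccps_config()) {
  curve <- as_polyline(curve)
  stopifnot(inherits(projection, "ccps_projection"), projection$m == nrow(curve))
  points <- projection$points
  cx <- mean(points$x); cy <- mean(points$y)
  m <- nrow(curve)
  dist_c <- sqrt((curve$x - cx)^2 + (curve$y - cy)^2)
  # small relative tolerance so a vertex sitting exactly on the radius
  # (e.g. clamped there by the optimizer) is not flagged by rounding
  outside <- dist_c > r * (1 + 1e-9)
  nb <- vapply(seq_len(m), function(i) length(.neighborhood_idx(projection, i)),
               integer(1))
  starved <- nb < config$min_projected_points
  cand <- which(outside | starved)
  cand <- cand[order(-dist_c[cand])]      # worst offenders first
  budget_total <- projection$total + config$delta_s
  .filter_impl(curve, cand, outside, points, budget_total)
}

# Greedy guarded removal: candidates indexed against the original curve.
.filter_impl <- function(curve, cand, outside, points, budget_total) {
  orig <- curve
  keep_mask <- rep(TRUE, nrow(orig))
  for (i in cand) {
    if (sum(keep_mask) <= 3L) break
    trial <- keep_mask
    trial[i] <- FALSE
    trial_curve <- .dedupe_consecutive(orig[trial, , drop = FALSE])
    if (nrow(trial_curve) < 3L) next
    if (outside[i]) {
      keep_mask <- trial
      next
    }
    new_total <- project_points(points, trial_curve)$total
    if (new_total <= budget_total) keep_mask <- trial
  }
  removed <- orig[!keep_mask, , drop = FALSE]
  out <- .dedupe_consecutive(orig[keep_mask, , drop = FALSE])
  structure(tibble::as_tibble(out), removed = removed)
}

.dedupe_consecutive <- function(curve) {
  repeat {
    n <- nrow(curve)
    if (n < 3L) break
    nxt <- c(seq_len(n)[-1], 1L)
    dup <- which(curve$x == curve$x[nxt] & curve$y == curve$y[nxt])
    if (length(dup) == 0L) break
    curve <- curve[-dup[1L], , drop = FALSE]
  }
  curve
}

#' Whole-loop stop rule for the principal-curve fit
#'
#' The fit stops when the number of segments exceeds
#' `beta_stop * n^(1/3) * delta_n^(-1/2) * r`.  A perfect fit
#' (`delta_n = 0`) stops immediately.
#'
#' @param num_segments current number of polygon segments.
#' @param n number of seed points.
#' @param delta_n mean squared projection distance.
#' @param r data radius.
#' @param config a [ccps_config()].
#' @return logical.
#' @export
stop_whole_loop <- function(num_segments, n, delta_n, r, config = ccps_config()) {
  stopifnot(delta_n >= 0, r > 0)
  if (delta_n == 0) return(TRUE)
  num_segments > config$beta_stop * n^(1 / 3) * delta_n^(-1 / 2) * r
}

#' Order a closed curve into a vertex sequence
#'
#' Orients the curve counterclockwise, rotates it to start from the
#' vertex with the largest `x` (ties: largest `y`), assigns the curve
#' parameter `t_i = (i - 1) / m`, and appends a duplicate of the first
#' vertex at `t = 1` so the closure is explicit in the training data.
#'
#' @param curve polyline in normalized coordinates.
#' @param params the `zscore_params` mapping back to pixels (attached as
#'   the `"norm_params"` attribute).
#' @return tibble with columns `t`, `x`, `y` (normalized coordinates).
#' @export
to_vertex_sequence <- function(curve, params) {
  curve <- polyline_ccw(as_polyline(curve))
  m <- nrow(curve)
  start <- order(-curve$x, -curve$y)[1L]
  idx <- c(seq(start, m), if (start > 1L) seq_len(start - 1L))
  curve <- curve[idx, ]
  out <- tibble::tibble(t = (seq_len(m) - 1) / m, x = curve$x, y = curve$y)
  out <- dplyr::bind_rows(out, tibble::tibble(t = 1, x = curve$x[1L], y = curve$y[1L]))
  structure(out, norm_params = params)
}

#' Fit the constrained closed polygonal principal curve
#'
#' Stage one of the segmentation pipeline.  The seed points are Z-score
#' normalized, the curve starts from a small closed square around the
#' data centroid, and the fit alternates projection, vertex-position
#' optimization, vertex insertion into the worst segment, and filtering
#' of abnormal vertices, until the whole-loop segment bound is met, the
#' outer-loop improvement drops below `delta_s`, or the segment cap is
#' reached.  The fit is fully deterministic.
#'
#' @param points data frame of seed points, columns `x`, `y` (pixels),
#'   at least 8 rows.
#' @param config a [ccps_config()].
#' @return an object of class `ccps_fit`: a list with `curve` (normalized
#'   polyline), `vertex_sequence` (tibble `t`, `x`, `y` + norm params),
#'   `norm_params`, `trace` (tibble `iter`, `n_vertices`, `delta_n`),
#'   `stopped_by`, `points` (the input), `config`.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 41)[-41]
#' pts <- data.frame(x = 100 + 50 * cos(theta), y = 100 + 50 * sin(theta))
#' fit <- fit_ccps(pts)
#' glance(fit)
#' @export
fit_ccps <- function(points, config = ccps_config()) {
  points <- validate_pointset(points)
  nz <- zscore_normalize(points)
  pn <- nz$points
  n <- nrow(pn)
  r <- data_radius(pn)
  curve <- init_square()
  trace <- list()
  total_prev <- Inf
  stopped_by <- "max_segments"
  for (iter in seq_len(config$max_segments)) {
    curve <- optimize_vertices(curve, pn, config, r = r)
    proj <- project_points(pn, curve)
    trace[[iter]] <- tibble::tibble(iter = iter, n_vertices = nrow(curve),
                                    delta_n = proj$delta_n)
    if (stop_whole_loop(nrow(curve), n, proj$delta_n, r, config)) {
      stopped_by <- "segment_bound"
      break
    }
    if (abs(total_prev - proj$total) < config$delta_s) {
      stopped_by <- "converged"
      break
    }
    total_prev <- proj$total
    if (nrow(curve) >= config$max_segments) {
      stopped_by <- "max_segments"
      break
    }
    grown <- tryCatch(insert_vertex(curve, proj),
      pcseg_no_splittable_segment = function(e) curve)
    # an insertion that worsens the fit beyond delta_s is reverted
    if (nrow(grown) > nrow(curve) &&
        project_points(pn, grown)$total <= proj$total + config$delta_s) {
      curve <- grown
    }
    proj2 <- project_points(pn, curve)
    curve <- filter_vertices(curve, proj2, r, config)
  }
  structure(list(
    curve = tibble::as_tibble(curve),
    vertex_sequence = to_vertex_sequence(curve, nz$params),
    norm_params = nz$params,
    trace = dplyr::bind_rows(trace),
    stopped_by = stopped_by,
    points = points,
    config = config
  ), class = "ccps_fit")
}

#' @export
print.ccps_fit <- function(x, ...) {
  cat("<ccps_fit> ", nrow(x$curve), " vertices, delta_n = ",
      signif(utils::tail(x$trace$delta_n, 1), 4),
      ", stopped by ", x$stopped_by, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_ccps
#' @param x,object a `ccps_fit`.
#' @param ... unused.
#' @export
tidy.ccps_fit <- function(x, ...) {
  vs <- x$vertex_sequence
  pix <- denormalize_points(vs, x$norm_params)
  tibble::tibble(t = vs$t, x = pix$x, y = pix$y,
                 x_norm = vs$x, y_norm = vs$y)
}

#' @rdname fit_ccps
#' @export
glance.ccps_fit <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$points),
    n_vertices = nrow(x$curve),
    delta_n = utils::tail(x$trace$delta_n, 1),
    iterations = nrow(x$trace),
    stopped_by = x$stopped_by
  )
}
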