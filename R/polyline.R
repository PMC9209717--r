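#' Closed polylines
#'
#' A closed polyline is an ordered set of vertices stored as a tibble with
#' columns `x` and `y`; the closing edge from the last vertex back to the
#' first is always implicit and never stored.  All polygon operations in
#' pcseg (projection, rasterization, area, orientation) treat the input
#' this way.
#'
#' @param x a data frame (or matrix) with columns/col-pairs `x`, `y`.
#' @return `as_polyline()` returns a validated tibble with columns `x`, `y`.
#' @examples
#' sq <- as_polyline(data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
#' polyline_area(sq)
#' @export
as_polyline <- function(x) {
  if (is.matrix(x)) x <- tibble::tibble(x = x[, 1], y = x[, 2])
  if (!all(c("x", "y") %in% names(x))) {
    rlang::abort("a polyline needs columns `x` and `y`", class = "pcseg_invalid_polyline")
  }
  out <- tibble::as_tibble(x)[, c("x", "y")]
  if (nrow(out) < 3L) {
    rlang::abort("a closed polyline needs at least 3 vertices",
      class = "pcseg_invalid_polyline")
  }
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    rlang::abort("polyline vertices must be finite", class = "pcseg_invalid_polyline")
  }
  nxt <- c(seq_len(nrow(out))[-1], 1L)
  if (any(out$x == out$x[nxt] & out$y == out$y[nxt])) {
    rlang::abort("consecutive polyline vertices must be distinct",
      class = "pcseg_invalid_polyline")
  }
  out
}

#' @describeIn as_polyline signed area by the shoelace formula (positive
#'   for counterclockwise vertex order in the x/y coordinate sense).
#' @param polyline a polyline tibble as returned by [as_polyline()].
#' @export
polyline_signed_area <- function(polyline) {
  nxt <- c(seq_len(nrow(polyline))[-1], 1L)
  sum(polyline$x * polyline$y[nxt] - polyline$x[nxt] * polyline$y) / 2
}

#' @describeIn as_polyline absolute enclosed area.
#' @export
polyline_area <- function(polyline) abs(polyline_signed_area(polyline))

#' @describeIn as_polyline reorder the vertices counterclockwise (no-op if
#'   already counterclockwise).
#' @export
polyline_ccw <- function(polyline) {
  if (polyline_signed_area(polyline) < 0) {
    polyline <- polyline[rev(seq_len(nrow(polyline))), ]
  }
  tibble::as_tibble(polyline)
}

# Squared distances from every point to every vertex and to every segment
# *interior* of a closed polyline.  Segment i joins vertex i to vertex
# i + 1 (mod m).  Projections falling on a segment endpoint are the
# vertex's business, so their segment distance is recorded as Inf.
# Returns list(vertex = n x m matrix, segment = n x m matrix).
.pl_dist2 <- function(px, py, polyline) {
  vx <- polyline$x
  vy <- polyline$y
  m <- length(vx)
  nxt <- c(seq_len(m)[-1], 1L)
  dvx <- outer(px, vx, "-")
  dvy <- outer(py, vy, "-")
  d2v <- dvx^2 + dvy^2
  ex <- vx[nxt] - vx
  ey <- vy[nxt] - vy
  len2 <- ex^2 + ey^2
  # projection parameter of each point on each (infinite) segment line
  u <- sweep(sweep(dvx, 2, ex, "*") + sweep(dvy, 2, ey, "*"), 2, len2, "/")
  foot_dx <- dvx - sweep(u, 2, ex, "*")
  foot_dy <- dvy - sweep(u, 2, ey, "*")
  d2s <- foot_dx^2 + foot_dy^2
  d2s[u <= 0 | u >= 1] <- Inf
  list(vertex = d2v, segment = d2s)
}

# Minimum squared distance from each point to a closed polyline
# (vertices and closing edge included).
dist2_to_polyline <- function(points, polyline) {
  d <- .pl_dist2(points$x, points$y, polyline)
  pmin(apply(d$vertex, 1, min), apply(d$segment, 1, min))
}
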