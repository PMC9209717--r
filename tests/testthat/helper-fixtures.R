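# Shared fixtures and independent oracles for the test suite.

toy_norm_params <- function(mu = c(x = 0, y = 0), sigma = c(x = 1, y = 1)) {
  structure(list(mu = mu, sigma = sigma), class = "zscore_params")
}

circle_points <- function(n = 40, r = 50, center = c(100, 100),
                          jitter = 0, seed = 1) {
  withr::with_seed(seed, {
    th <- 2 * pi * (seq_len(n) - 1) / n
    tibble::tibble(x = center[1] + (r + stats::rnorm(n, 0, jitter)) * cos(th),
                   y = center[2] + (r + stats::rnorm(n, 0, jitter)) * sin(th))
  })
}

# 16-vertex unit-circle vertex sequence (already "normalized")
circle_sequence <- function(m = 16) {
  th <- 2 * pi * (seq_len(m) - 1) / m
  out <- tibble::tibble(t = (seq_len(m + 1) - 1) / m,
                        x = cos(c(th, 0)), y = sin(c(th, 0)))
  attr(out, "norm_params") <- toy_norm_params()
  out
}

# Brute-force nearest-element projection, written independently of the
# package internals: plain loops, exact point-segment geometry.
brute_force_projection <- function(points, curve) {
  m <- nrow(curve)
  res_el <- character(nrow(points))
  res_ix <- integer(nrow(points))
  res_d2 <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    px <- points$x[p]; py <- points$y[p]
    best <- Inf; bel <- NA_character_; bix <- NA_integer_
    for (i in seq_len(m)) {            # vertices first (tie-break order)
      d2 <- (px - curve$x[i])^2 + (py - curve$y[i])^2
      if (d2 < best) { best <- d2; bel <- "vertex"; bix <- i }
    }
    for (i in seq_len(m)) {            # then segment interiors
      j <- if (i == m) 1L else i + 1L
      ex <- curve$x[j] - curve$x[i]; ey <- curve$y[j] - curve$y[i]
      u <- ((px - curve$x[i]) * ex + (py - curve$y[i]) * ey) / (ex^2 + ey^2)
      if (u > 0 && u < 1) {
        d2 <- (px - curve$x[i] - u * ex)^2 + (py - curve$y[i] - u * ey)^2
        if (d2 < best) { best <- d2; bel <- "segment"; bix <- i }
      }
    }
    res_el[p] <- bel; res_ix[p] <- bix; res_d2[p] <- best
  }
  tibble::tibble(element = res_el, index = res_ix, dist2 = res_d2)
}

# Brute-force even-odd point-in-polygon rasterizer (per-pixel loop).
brute_force_mask <- function(polygon, height, width) {
  mask <- matrix(0L, height, width)
  xs <- polygon$x; ys <- polygon$y; n <- length(xs)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      px <- col - 0.5; py <- row - 0.5
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((ys[i] > py) != (ys[j] > py)) {
          xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
          if (px < xint) inside <- !inside
        }
        j <- i
      }
      mask[row, col] <- as.integer(inside)
    }
  }
  mask
}

random_polyline <- function(n_vertices, scale = 50, center = c(32, 32), seed) {
  withr::with_seed(seed, {
    th <- sort(stats::runif(n_vertices, 0, 2 * pi))
    r <- stats::runif(n_vertices, 0.3, 1) * scale / 2
    tibble::tibble(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
  })
}

# max over both directions of point-to-polyline distance between two
# closed polylines, each sampled densely along its edges
polyline_hausdorff <- function(a, b, samples_per_edge = 20) {
  densify <- function(p) {
    m <- nrow(p); out <- NULL
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      u <- seq(0, 1, length.out = samples_per_edge + 1)[-(samples_per_edge + 1)]
      out <- rbind(out, cbind(p$x[i] + u * (p$x[j] - p$x[i]),
                              p$y[i] + u * (p$y[j] - p$y[i])))
    }
    tibble::tibble(x = out[, 1], y = out[, 2])
  }
  d1 <- max(pcseg:::dist2_to_polyline(densify(a), b))
  d2 <- max(pcseg:::dist2_to_polyline(densify(b), a))
  sqrt(max(d1, d2))
}
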