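test_that("z-score normalization matches direct evaluation and inverts exactly", {
  # each corner duplicated so the op's n >= 8 precondition is met
  pts <- tibble::tibble(x = rep(c(0, 2, 0, 2), 2), y = rep(c(0, 0, 2, 2), 2))
  nz <- zscore_normalize(pts)
  expect_equal(nz$params$mu, c(x = 1, y = 1))
  expect_equal(nz$params$sigma, c(x = 1, y = 1))
  expect_equal(sort(unique(nz$points$x)), c(-1, 1))
  expect_equal(sort(unique(nz$points$y)), c(-1, 1))

  # a set already standardized is a fixed point
  again <- zscore_normalize(nz$points)
  expect_lt(max(abs(again$points$x - nz$points$x)), 1e-9)
  expect_lt(max(abs(again$points$y - nz$points$y)), 1e-9)

  # round trip on a random set
  rnd <- circle_points(25, jitter = 3, seed = 4)
  nz2 <- zscore_normalize(rnd)
  back <- denormalize_points(nz2$points, nz2$params)
  expect_lt(max(abs(back$x - rnd$x)), 1e-9)
  expect_lt(max(abs(back$y - rnd$y)), 1e-9)
  expect_lt(abs(mean(nz2$points$x)), 1e-9)
  expect_lt(abs(sqrt(mean(nz2$points$y^2)) - 1), 1e-9)

  # direct denormalization example: x = mu + sigma * x'
  out <- denormalize_points(tibble::tibble(x = 1, y = -1),
                            toy_norm_params(c(x = 5, y = 5), c(x = 2, y = 3)))
  expect_equal(c(out$x, out$y), c(7, 2))

  expect_error(zscore_normalize(tibble::tibble(x = rep(1, 8), y = rep(1, 8))),
               class = "pcseg_degenerate_variance")
  expect_error(zscore_normalize(circle_points(5)), class = "pcseg_too_few_points")
})

test_that("initial square has the canonical vertices and symmetry", {
  sq <- init_square()
  expect_equal(nrow(sq), 4L)
  expect_equal(sq$x, c(0.1, -0.1, -0.1, 0.1))
  expect_equal(sq$y, c(0.1, 0.1, -0.1, -0.1))
  # symmetric under point reflection
  neg <- tibble::tibble(x = -sq$x, y = -sq$y)
  expect_setequal(paste(neg$x, neg$y), paste(sq$x, sq$y))
  expect_gt(polyline_signed_area(sq), 0)   # counterclockwise
})

test_that("projection assigns nearest elements and matches brute force", {
  sq <- init_square()
  # a point coincident with a vertex
  pr <- project_points(tibble::tibble(x = c(0.1, 0), y = c(0.1, 0)), sq)
  expect_equal(pr$assignment$element[1], "vertex")
  expect_equal(pr$assignment$dist2[1], 0)
  # the origin is 0.1 from every edge of the square
  expect_equal(pr$assignment$dist2[2], 0.01)
  expect_equal(pr$delta_n, mean(pr$assignment$dist2))
  expect_equal(pr$total, sum(pr$assignment$dist2))

  for (seed in 1:5) {
    curve <- random_polyline(sample(4:10, 1), seed = seed + 100)
    pts <- withr::with_seed(seed, tibble::tibble(x = stats::runif(50, 0, 64),
                                                 y = stats::runif(50, 0, 64)))
    got <- project_points(pts, curve)$assignment
    want <- brute_force_projection(pts, curve)
    expect_equal(got$element, want$element)
    expect_equal(got$index, want$index)
    expect_equal(got$dist2, want$dist2, tolerance = 1e-12)
  }
})

test_that("data radius is the max centroid distance", {
  expect_equal(data_radius(circle_points(60, r = 1, center = c(0, 0))), 1,
               tolerance = 1e-9)
  expect_equal(data_radius(tibble::tibble(x = 5, y = 7)), 0)
  expect_equal(data_radius(tibble::tibble(x = c(0, 2), y = c(0, 0))), 1)
})

test_that("vertex optimization moves vertices to clusters and never worsens", {
  set.seed(3)
  cl <- rbind(cbind(rnorm(10, 0, 0.02), rnorm(10, 0, 0.02)),
              cbind(rnorm(10, 2, 0.02), rnorm(10, 0, 0.02)),
              cbind(rnorm(10, 1, 0.02), rnorm(10, 2, 0.02)))
  pts <- tibble::tibble(x = cl[, 1], y = cl[, 2])
  tri <- tibble::tibble(x = c(0.4, 1.6, 1), y = c(0.3, 0.3, 1.6))
  opt <- optimize_vertices(tri, pts)
  before <- project_points(pts, tri)
  after <- project_points(pts, opt)
  expect_lt(after$total, before$total)
  expect_lte(after$delta_n, before$delta_n + 1e-12)
  # vertices end near the cluster centroids
  cents <- rbind(colMeans(cl[1:10, ]), colMeans(cl[11:20, ]), colMeans(cl[21:30, ]))
  for (i in 1:3) {
    d <- min(sqrt((opt$x - cents[i, 1])^2 + (opt$y - cents[i, 2])^2))
    expect_lt(d, 0.05)
  }
  # at least as good as a 5x5 grid-search repositioning oracle
  grid_best <- tri
  for (i in 1:3) {
    cand_x <- seq(min(pts$x), max(pts$x), length.out = 5)
    cand_y <- seq(min(pts$y), max(pts$y), length.out = 5)
    best_tot <- project_points(pts, grid_best)$total
    for (cx in cand_x) for (cy in cand_y) {
      cand <- grid_best; cand$x[i] <- cx; cand$y[i] <- cy
      others <- cand[-i, ]
      if (any(others$x == cx & others$y == cy)) next  # degenerate candidate
      tot <- project_points(pts, cand)$total
      if (tot < best_tot) { best_tot <- tot; grid_best <- cand }
    }
  }
  expect_lte(after$total, project_points(pts, grid_best)$total + 1e-9)

  # a curve at a local optimum is returned essentially unchanged
  opt2 <- optimize_vertices(opt, pts)
  expect_lte(project_points(pts, opt2)$total,
             project_points(pts, opt)$total + 1e-12)
})

test_that("vertex insertion splits the worst segment", {
  sq <- tibble::tibble(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
  # misfit concentrated along the bottom edge (segment 3->4 is at y=-1)
  pts <- tibble::tibble(x = c(seq(-0.8, 0.8, length.out = 8), 0.99, -0.99),
                        y = c(rep(-1.6, 8), 1, 1))
  pr <- project_points(pts, sq)
  grown <- insert_vertex(sq, pr)
  expect_equal(nrow(grown), 5L)
  # the new vertex sits at the centroid of the bottom-edge points
  new_v <- dplyr::anti_join(grown, sq, by = c("x", "y"))
  expect_equal(nrow(new_v), 1L)
  expect_equal(new_v$y, -1.6)
  # no original vertex is removed by insertion
  expect_equal(nrow(dplyr::semi_join(sq, grown, by = c("x", "y"))), 4L)

  # error when no segment has two projected points
  tight <- tibble::tibble(x = c(1, -1, 0), y = c(0.2, 0.2, -0.4))
  ptsv <- tibble::tibble(x = c(1, -1, 0), y = c(0.2, 0.2, -0.4))
  prv <- project_points(ptsv, tight)
  expect_error(insert_vertex(tight, prv), class = "pcseg_no_splittable_segment")
})

test_that("vertex filtering removes the two abnormal situations", {
  pts <- circle_points(40, r = 1, center = c(0, 0))
  r <- data_radius(pts)
  good <- tibble::tibble(x = 1.0 * cos(2 * pi * (0:5) / 6),
                         y = 1.0 * sin(2 * pi * (0:5) / 6))
  # a vertex at twice the data radius is removed
  bad <- good; bad$x[1] <- 2 * r; bad$y[1] <- 0
  filt <- filter_vertices(bad, project_points(pts, bad), r)
  expect_equal(nrow(filt), 5L)
  expect_false(any(filt$x > r))
  expect_equal(nrow(attr(filt, "removed")), 1L)

  # a redundant vertex whose neighborhood captures fewer than 5 points
  # is removed: all data hug the top path, the bottom vertex serves none
  lin_pts <- tibble::tibble(x = seq(0, 7, length.out = 20), y = rep(0, 20))
  lin_curve <- tibble::tibble(x = c(0, 3.5, 7, 3.5), y = c(0, 0.012, 0, -1))
  rl <- data_radius(lin_pts)
  prl <- project_points(lin_pts, lin_curve)
  expect_lt(length(pcseg:::.neighborhood_idx(prl, 4)), 5)
  filt2 <- filter_vertices(lin_curve, prl, rl)
  expect_false(any(filt2$y == -1))
  expect_equal(nrow(filt2), 3L)

  # a fully healthy curve is unchanged
  filt3 <- filter_vertices(good, project_points(pts, good), r)
  expect_equal(nrow(filt3), 6L)
  expect_equal(nrow(attr(filt3, "removed")), 0L)
})

test_that("whole-loop stop rule matches direct evaluation", {
  cfg <- ccps_config()
  # threshold = 0.3 * 1000^(1/3) * 0.04^(-1/2) * 1.5 = 22.5
  expect_true(stop_whole_loop(23, 1000, 0.04, 1.5, cfg))
  expect_false(stop_whole_loop(22, 1000, 0.04, 1.5, cfg))
  expect_true(stop_whole_loop(4, 1000, 0, 1.5, cfg))   # perfect fit
})

test_that("vertex sequencing is canonical and closed", {
  sq <- tibble::tibble(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
  vs <- to_vertex_sequence(sq, toy_norm_params())
  expect_equal(vs$t, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(c(vs$x[1], vs$y[1]), c(1, 1))     # max-x, tie -> max-y
  expect_equal(vs[nrow(vs), c("x", "y")], vs[1, c("x", "y")])
  expect_true(all(diff(vs$t) > 0))
  # rotated storage order gives the identical sequence
  rot <- sq[c(3, 4, 1, 2), ]
  expect_equal(to_vertex_sequence(rot, toy_norm_params()), vs,
               ignore_attr = TRUE)
  # reversed (clockwise) storage too
  rev <- sq[4:1, ]
  expect_equal(to_vertex_sequence(rev, toy_norm_params()), vs,
               ignore_attr = TRUE)
})

test_that("full principal-curve fit recovers shapes and is deterministic", {
  pts <- circle_points(200, r = 50, center = c(120, 130), jitter = 1, seed = 9)
  fit <- fit_ccps(pts)
  expect_s3_class(fit, "ccps_fit")
  tr <- fit$trace
  expect_lt(tr$delta_n[nrow(tr)], tr$delta_n[1])
  # delta_n non-increasing within the delta_s tolerance
  expect_true(all(diff(tr$delta_n) <= fit$config$delta_s + 1e-12))
  # curve closed and valid throughout
  expect_gte(nrow(fit$curve), 3L)
  expect_silent(as_polyline(fit$curve))

  # identical rerun
  fit2 <- fit_ccps(pts)
  expect_identical(fit$vertex_sequence, fit2$vertex_sequence)

  # noiseless square recovered within 1e-2 Hausdorff (normalized units)
  side <- seq(0, 1, length.out = 31)[-31]
  sqp <- rbind(cbind(side, 0), cbind(1, side), cbind(1 - side, 1), cbind(0, 1 - side))
  spts <- tibble::tibble(x = sqp[, 1] * 100, y = sqp[, 2] * 100)
  sfit <- fit_ccps(spts)
  truth <- normalize_points(tibble::tibble(x = c(0, 1, 1, 0) * 100,
                                           y = c(0, 0, 1, 1) * 100),
                            sfit$norm_params)
  expect_lt(polyline_hausdorff(sfit$curve, truth), 1e-2)

  expect_error(fit_ccps(circle_points(6)), class = "pcseg_too_few_points")

  g <- glance(fit)
  expect_equal(g$n_points, 200L)
  td <- tidy(fit)
  expect_true(all(c("t", "x", "y") %in% names(td)))
  # tidy() reports pixel coordinates near the original circle
  expect_lt(abs(mean(range(td$x)) - 120), 5)
})
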