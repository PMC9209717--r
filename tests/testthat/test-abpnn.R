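make_scaler <- function(seq, margin = 0.1) {
  contour_scaler(seq, margin = margin, norm_params = toy_norm_params())
}

random_params <- function(q, seed, scale = 1) {
  withr::with_seed(seed, abpnn_params(
    omega = stats::runif(q, -scale, scale), tau = stats::runif(q, -scale, scale),
    A = matrix(stats::runif(2 * q, -scale, scale), q, 2),
    b = stats::runif(2, -scale, scale)))
}

random_sequence <- function(n, seed) {
  withr::with_seed(seed, {
    out <- tibble::tibble(t = seq(0, 1, length.out = n),
                          x = stats::rnorm(n), y = stats::rnorm(n))
    attr(out, "norm_params") <- toy_norm_params()
    out
  })
}

test_that("flatten/unflatten is an exact involution with the 4q+2 layout", {
  p <- random_params(10, 1)
  v <- abpnn_flatten(p)
  expect_length(v, 42L)
  p2 <- abpnn_unflatten(v, 10)
  expect_equal(p2, p)
  expect_error(abpnn_unflatten(v[-1], 10), class = "pcseg_length_mismatch")
})

test_that("the forward pass matches hand evaluation and stays in (-1, 1)", {
  pz <- abpnn_params(1, 0, cbind(0, 0), c(0, 0))
  expect_equal(as.numeric(abpnn_forward(pz, 0.3)), c(0, 0))

  p1 <- abpnn_params(1, 0, cbind(1, 1), c(0, 0))
  out <- abpnn_forward(p1, 0)   # h = sigmoid(0) = 0.5, g = tanh(0.5)
  expect_equal(as.numeric(out), rep(tanh(0.5), 2), tolerance = 1e-12)

  p <- random_params(7, 3, scale = 5)
  G <- abpnn_forward(p, seq(0, 1, length.out = 101))
  expect_true(all(abs(G) < 1))
  expect_equal(dim(G), c(101L, 2L))
})

test_that("the sum-of-squares error behaves like a squared distance", {
  seq <- random_sequence(9, 5)
  sc <- make_scaler(seq)
  p <- random_params(4, 6)
  # invariant to entry order
  perm <- withr::with_seed(8, sample.int(9))
  seq_p <- seq[perm, ]
  expect_equal(abpnn_sse(p, seq, sc), abpnn_sse(p, seq_p, sc))
  expect_gte(abpnn_sse(p, seq, sc), 0)

  # single entry, one axis off by 0.2 -> E = 0.04: build the target by
  # inverting the scaler around the model's own output
  p1 <- abpnn_params(1, 0, cbind(1, 1), c(0, 0))
  out <- map_output(abpnn_forward(p1, 0.5))
  sc1 <- structure(list(min = c(x = -1, y = -1), max = c(x = 1, y = 1),
                        margin = 0.1, norm_params = toy_norm_params()),
                   class = "contour_scaler")
  target <- unscale_coords(tibble::tibble(x = out[1] - 0.2, y = out[2]), sc1)
  seq1 <- tibble::tibble(t = 0.5, x = target$x, y = target$y)
  expect_equal(abpnn_sse(p1, seq1, sc1), 0.04, tolerance = 1e-12)
  # and zero when targets equal the model output exactly
  t0 <- unscale_coords(tibble::tibble(x = out[1], y = out[2]), sc1)
  expect_equal(abpnn_sse(p1, tibble::tibble(t = 0.5, x = t0$x, y = t0$y), sc1), 0)
})

test_that("the analytic gradient matches central finite differences", {
  for (case in 1:20) {
    q <- sample(2:6, 1)
    p <- random_params(q, case + 50, scale = 2)
    seq <- random_sequence(sample(5:12, 1), case + 150)
    sc <- make_scaler(seq)
    v <- abpnn_flatten(p)
    g <- abpnn_gradient(p, seq, sc)
    fd <- vapply(seq_along(v), function(i) {
      h <- 1e-5
      vp <- v; vp[i] <- vp[i] + h
      vm <- v; vm[i] <- vm[i] - h
      (abpnn_sse(abpnn_unflatten(vp, q), seq, sc) -
         abpnn_sse(abpnn_unflatten(vm, q), seq, sc)) / (2 * h)
    }, numeric(1))
    rel <- max(abs(g$grad - fd) / pmax(abs(fd), 1e-4))
    expect_lt(rel, 1e-6)
    expect_equal(g$error, abpnn_sse(p, seq, sc))
  }
})

test_that("a small gradient step descends; a perfect fit is a fixed point", {
  seq <- random_sequence(10, 21)
  sc <- make_scaler(seq)
  p <- random_params(5, 22)
  st <- backprop_epoch(p, seq, sc, eta = 1e-4)
  expect_equal(st$error, abpnn_sse(p, seq, sc))
  expect_lt(abpnn_sse(st$params, seq, sc), st$error)

  # targets manufactured to equal the model output exactly -> zero gradient
  p1 <- random_params(3, 23)
  tt <- seq(0, 1, length.out = 7)
  out <- map_output(abpnn_forward(p1, tt))
  sc1 <- structure(list(min = c(x = -1, y = -1), max = c(x = 1, y = 1),
                        margin = 0.1, norm_params = toy_norm_params()),
                   class = "contour_scaler")
  tgt <- unscale_coords(tibble::tibble(x = out[, 1], y = out[, 2]), sc1)
  seq1 <- tibble::tibble(t = tt, x = tgt$x, y = tgt$y)
  st1 <- backprop_epoch(p1, seq1, sc1, eta = 0.5)
  expect_equal(st1$error, 0, tolerance = 1e-24)
  expect_equal(abpnn_flatten(st1$params), abpnn_flatten(p1))
})

test_that("the learning-rate law multiplies by alpha or beta and clamps", {
  expect_equal(adapt_learning_rate(0.5, 1, 2), 0.75)       # error fell
  expect_equal(adapt_learning_rate(0.5, 2, 1), 0.25)       # error rose
  expect_equal(adapt_learning_rate(0.37, 1, 1), 0.37)      # unchanged
  expect_equal(adapt_learning_rate(8, 1, 2), 10)           # capped above
  expect_equal(adapt_learning_rate(1.5e-8, 2, 1), 1e-8)    # floored below
})

test_that("training fits a circle, obeys its own traces, and is deterministic", {
  vs <- circle_sequence(16)
  fit <- train_abpnn(vs, abpnn_config(seed = 1))
  expect_s3_class(fit, "abpnn_fit")
  expect_lt(fit$final_error, 0.05)
  expect_lte(fit$final_error, fit$init_error)
  expect_equal(nrow(fit$trace), 1000L)

  # the recorded learning-rate path replays exactly from the error path
  tr <- fit$trace
  expect_equal(tr$eta[1], 0.5)
  e_prev <- fit$init_error
  for (k in seq_len(nrow(tr) - 1)) {
    expect_equal(tr$eta[k + 1],
                 adapt_learning_rate(tr$eta[k], tr$error[k], e_prev))
    e_prev <- tr$error[k]
  }

  fit2 <- train_abpnn(vs, abpnn_config(seed = 1))
  expect_identical(abpnn_flatten(fit$params), abpnn_flatten(fit2$params))
  expect_identical(fit$trace, fit2$trace)

  g <- glance(fit)
  expect_equal(g$q, 10L)
  td <- tidy(fit)
  expect_equal(nrow(td), 42L)
  expect_true("omega1" %in% td$term)
})

test_that("a sequence generated by a known small network is recovered", {
  gen <- withr::with_seed(42, abpnn_params(
    omega = stats::runif(3, -3, 3), tau = stats::runif(3, -1, 1),
    A = matrix(stats::runif(6, -1.5, 1.5), 3, 2), b = stats::runif(2, -0.5, 0.5)))
  tt <- seq(0, 1, length.out = 21)
  G <- abpnn_forward(gen, tt)
  seq <- tibble::tibble(t = tt, x = G[, 1], y = G[, 2])
  attr(seq, "norm_params") <- toy_norm_params()
  fit <- train_abpnn(seq, abpnn_config(seed = 2))
  expect_lt(fit$final_error, 0.02)
  # the fitted curve tracks the generator curve closely in (0,1) space
  tfine <- seq(0, 1, length.out = 100)
  sc <- fit$scaler
  pred <- map_output(abpnn_forward(fit$params, tfine))
  truth <- as.matrix(scale_coords(
    tibble::tibble(x = abpnn_forward(gen, tfine)[, 1],
                   y = abpnn_forward(gen, tfine)[, 2]), sc))
  expect_lt(stats::median(abs(pred - truth)), 0.05)
})
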