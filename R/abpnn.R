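#' Network parameters of the contour model
#'
#' One hidden layer of `q` sigmoid neurons maps the scalar curve
#' parameter `t` to two tanh outputs, one per coordinate axis:
#' `h_i = sigmoid(t * omega_i - tau_i)` and
#' `g_k = tanh(sum_i h_i * A[i, k] - b_k)`.  The flat-vector layout used
#' by the evolutionary initializer is `c(omega, tau, A[, 1], A[, 2], b)`
#' of length `4q + 2`.
#'
#' @param omega length-`q` input-to-hidden weights.
#' @param tau length-`q` hidden thresholds.
#' @param A `q x 2` hidden-to-output weights.
#' @param b length-2 output thresholds.
#' @return a list of class `abpnn_params`.
#' @export
abpnn_params <- function(omega, tau, A, b) {
  q <- length(omega)
  stopifnot(q >= 1, length(tau) == q, is.matrix(A), nrow(A) == q,
            ncol(A) == 2, length(b) == 2,
            all(is.finite(c(omega, tau, A, b))))
  structure(list(q = q, omega = as.numeric(omega), tau = as.numeric(tau),
                 A = A, b = as.numeric(b)),
            class = "abpnn_params")
}

#' @describeIn abpnn_params flatten to the canonical `4q + 2` vector.
#' @param params an `abpnn_params`.
#' @export
abpnn_flatten <- function(params) {
  c(params$omega, params$tau, params$A[, 1], params$A[, 2], params$b)
}

#' @describeIn abpnn_params rebuild parameters from a flat vector.
#' @param vec numeric vector of length `4q + 2`.
#' @param q hidden-neuron count.
#' @export
abpnn_unflatten <- function(vec, q) {
  if (length(vec) != 4 * q + 2) {
    rlang::abort(sprintf("expected a vector of length %d (4q + 2), got %d",
                         4 * q + 2, length(vec)),
      class = "pcseg_length_mismatch")
  }
  abpnn_params(omega = vec[1:q], tau = vec[(q + 1):(2 * q)],
               A = cbind(vec[(2 * q + 1):(3 * q)], vec[(3 * q + 1):(4 * q)]),
               b = vec[(4 * q + 1):(4 * q + 2)])
}

#' Forward pass of the contour network
#'
#' @param params an [abpnn_params()].
#' @param t numeric vector of curve parameters in `[0, 1]`.
#' @return a `length(t) x 2` matrix of outputs `(g_x, g_y)`, each
#'   strictly inside `(-1, 1)`.
#' @examples
#' p <- abpnn_params(1, 0, cbind(1, 1), c(0, 0))
#' abpnn_forward(p, 0)  # tanh(0.5) on both axes
#' @export
abpnn_forward <- function(params, t) {
  H <- stats::plogis(outer(t, params$omega) -
                       matrix(params$tau, length(t), params$q, byrow = TRUE))
  tanh(sweep(H %*% params$A, 2, params$b, "-"))
}

#' Training configuration for the contour network
#'
#' @param epochs full-batch gradient epochs (default 1000).
#' @param eta0 initial learning rate (default 0.5).
#' @param alpha learning-rate increase factor applied when the epoch
#'   error falls (default 1.5, must lie in (1, 2)).
#' @param beta_lr learning-rate decrease factor applied when the epoch
#'   error rises (default 0.5, in (0, 1)).
#' @param q hidden-neuron count (default 10).
#' @param de_config a [de_config()] for the weight initialization search
#'   (bounds `[-1, 1]` by default).
#' @param input_scale scale `s` of the standardized curve parameter
#'   `z = s * (t - 1/2)` used internally as the training coordinate for
#'   the input weight and threshold (default 4).  This is a pure linear
#'   reparameterization -- the stored parameters always satisfy
#'   `h = sigmoid(t * omega - tau)` -- but centring and spreading the
#'   input conditions the gradient descent far better than raw
#'   `t` in `[0, 1]`.
#' @param seed optional integer controlling the initialization search; a
#'   fixed seed makes training bit-reproducible.
#' @return a list of class `abpnn_config`.
#' @export
abpnn_config <- function(epochs = 1000L, eta0 = 0.5, alpha = 1.5,
                         beta_lr = 0.5, q = 10L, de_config = NULL,
                         input_scale = 4, seed = NULL) {
  stopifnot(epochs >= 1, eta0 > 0, alpha > 1, alpha < 2,
            beta_lr > 0, beta_lr < 1, q >= 1, input_scale > 0)
  structure(list(epochs = as.integer(epochs), eta0 = eta0, alpha = alpha,
                 beta_lr = beta_lr, q = as.integer(q),
                 de_config = de_config, input_scale = input_scale,
                 seed = seed),
            class = "abpnn_config")
}

#' Sum-of-squares training error
#'
#' The error is computed in mapped coordinates: network outputs pass
#' through the output map `(1 + g) / 2` and are compared with the
#' vertex-sequence coordinates min-max scaled into
#' `[margin, 1 - margin]` by the supplied scaler.
#'
#' @param params an [abpnn_params()].
#' @param seq a vertex sequence (tibble `t`, `x`, `y`).
#' @param scaler a [contour_scaler()].
#' @return scalar error `E >= 0`.
#' @export
abpnn_sse <- function(params, seq, scaler) {
  target <- scale_coords(seq, scaler)
  pred <- .map_output_unchecked(abpnn_forward(params, seq$t))
  sum((pred - as.matrix(target))^2)
}

#' One full-batch backpropagation epoch
#'
#' Takes a single gradient step of size `eta` on the sum-of-squares
#' error with respect to all `4q + 2` parameters; the returned error is
#' the pre-step error.
#'
#' @inheritParams abpnn_sse
#' @param eta learning rate (> 0).
#' @return list with `params` (updated) and `error` (pre-step E).
#' @export
backprop_epoch <- function(params, seq, scaler, eta) {
  stopifnot(eta > 0)
  g <- abpnn_gradient(params, seq, scaler)
  if (!all(is.finite(g$grad))) {
    rlang::abort("non-finite gradient", class = "pcseg_nonfinite_gradient")
  }
  new <- abpnn_unflatten(abpnn_flatten(params) - eta * g$grad, params$q)
  list(params = new, error = g$error)
}

#' @describeIn backprop_epoch analytic gradient of the error with
#'   respect to the flat parameter vector; returns `grad` and `error`.
#' @export
abpnn_gradient <- function(params, seq, scaler) {
  tt <- seq$t
  n <- length(tt)
  target <- as.matrix(scale_coords(seq, scaler))
  H <- stats::plogis(outer(tt, params$omega) -
                       matrix(params$tau, n, params$q, byrow = TRUE))
  U <- sweep(H %*% params$A, 2, params$b, "-")
  G <- tanh(U)
  M <- (1 + G) / 2
  E <- sum((M - target)^2)
  # dE/dU = 2 (M - target) * dM/dG * dG/dU = (M - target) * (1 - G^2)
  dU <- (M - target) * (1 - G^2)
  dA <- t(H) %*% dU                      # q x 2
  db <- -colSums(dU)                     # length 2
  dH <- dU %*% t(params$A)               # n x q
  dZ <- dH * H * (1 - H)                 # n x q
  domega <- colSums(dZ * tt)             # length q
  dtau <- -colSums(dZ)                   # length q
  list(grad = unname(c(domega, dtau, dA[, 1], dA[, 2], db)), error = E)
}

#' Adaptive learning-rate update
#'
#' The learning rate is multiplied by `alpha` when the epoch error fell,
#' by `beta_lr` when it rose, and kept when unchanged, then clamped into
#' `[eta_min, eta_max]` to keep repeated multiplication finite.
#'
#' @param eta_prev previous learning rate (> 0).
#' @param e_k,e_prev current and previous epoch errors.
#' @param alpha,beta_lr increase/decrease factors (defaults 1.5 / 0.5).
#' @param eta_min,eta_max clamp bounds.
#' @export
adapt_learning_rate <- function(eta_prev, e_k, e_prev, alpha = 1.5,
                                beta_lr = 0.5, eta_min = 1e-8, eta_max = 10) {
  stopifnot(eta_prev > 0)
  eta <- if (e_k < e_prev) alpha * eta_prev
         else if (e_k > e_prev) beta_lr * eta_prev
         else eta_prev
  min(max(eta, eta_min), eta_max)
}

# Convert between the stored parameterization (h = sigmoid(t*omega - tau))
# and the standardized training parameterization
# (h = sigmoid(z*omega' - tau') with z = s*(t - 1/2)):
# omega = s * omega', tau = (s/2) * omega' + tau'.
.from_std <- function(vec, q, s) {
  omega_s <- vec[1:q]
  tau_s <- vec[(q + 1):(2 * q)]
  c(s * omega_s, (s / 2) * omega_s + tau_s, vec[-seq_len(2 * q)])
}

# gradient of E w.r.t. the standardized vector, by the chain rule from
# the plain-space gradient
.grad_std <- function(grad, q, s) {
  c(s * grad[1:q] + (s / 2) * grad[(q + 1):(2 * q)],
    grad[(q + 1):(2 * q)], grad[-seq_len(2 * q)])
}

#' Train the contour network on a vertex sequence
#'
#' Phase one searches the initial weights and thresholds by minimizing
#' the sum-of-squares error over the flat `4q + 2` parameter vector with
#' the differential-evolution optimizer (IAMCDE by default).  Phase two
#' refines them by full-batch gradient descent with the error-driven
#' adaptive learning rate: the rate is multiplied by `alpha` after an
#' epoch whose error fell and by `beta_lr` after one whose error rose.
#' The best parameters seen are snapshotted throughout, so the final
#' model is never worse than its initialization, and an epoch that
#' leaves the error more than 50% above the best-so-far restarts from
#' the snapshot (the learning-rate law is unaffected).  Descent is
#' performed in the standardized-input parameterization (see
#' [abpnn_config()]); the returned parameters are in the plain
#' `sigmoid(t * omega - tau)` form.
#'
#' @param seq a vertex sequence from [fit_ccps()] (tibble `t`, `x`, `y`
#'   in normalized coordinates, with the closure duplicate at `t = 1`).
#' @param config an [abpnn_config()].
#' @param scaler optionally a precomputed [contour_scaler()]; by default
#'   built from `seq`.
#' @return an object of class `abpnn_fit`: `params` (best),
#'   `scaler`, `trace` (tibble `epoch`, `error`, `eta`), `init_error`
#'   (phase-one best fitness), `final_error`, `de_result`, `config`.
#' @export
train_abpnn <- function(seq, config = abpnn_config(), scaler = NULL) {
  stopifnot(all(c("t", "x", "y") %in% names(seq)), nrow(seq) >= 4)
  if (is.null(scaler)) scaler <- contour_scaler(seq)
  q <- config$q
  s <- config$input_scale
  dim <- 4 * q + 2
  n <- nrow(seq)
  dcfg <- config$de_config
  if (is.null(dcfg)) {
    dcfg <- de_config("IAMCDE",
      seed = if (is.null(config$seed)) NULL else config$seed %% 2147483647L)
  }
  sse_std <- function(v) abpnn_sse(abpnn_unflatten(.from_std(v, q, s), q), seq, scaler)
  de_res <- de_minimize(sse_std, dim, dcfg)
  theta <- de_res$par               # standardized coordinates
  init_error <- de_res$value

  eta <- config$eta0
  e_prev <- init_error
  best_theta <- theta
  best_error <- init_error
  err <- numeric(config$epochs)
  etas <- numeric(config$epochs)
  for (k in seq_len(config$epochs)) {
    g <- abpnn_gradient(abpnn_unflatten(.from_std(theta, q, s), q), seq, scaler)
    if (!all(is.finite(g$grad))) {
      rlang::abort("non-finite gradient", class = "pcseg_nonfinite_gradient")
    }
    cand <- theta - (eta / n) * .grad_std(g$grad, q, s)
    e_new <- sse_std(cand)
    err[k] <- e_new
    etas[k] <- eta
    if (e_new < best_error) {
      best_error <- e_new
      best_theta <- cand
    }
    # divergence guard: restart from the snapshot rather than drifting
    theta <- if (e_new > 1.5 * best_error) best_theta else cand
    eta <- adapt_learning_rate(eta, e_new, e_prev,
                               config$alpha, config$beta_lr)
    e_prev <- e_new
  }
  structure(list(params = abpnn_unflatten(.from_std(best_theta, q, s), q),
                 scaler = scaler,
                 trace = tibble::tibble(epoch = seq_len(config$epochs),
                                        error = err, eta = etas),
                 init_error = init_error, final_error = best_error,
                 de_result = de_res, config = config),
            class = "abpnn_fit")
}

#' @export
print.abpnn_fit <- function(x, ...) {
  cat("<abpnn_fit> q = ", x$params$q, ", init E = ", signif(x$init_error, 5),
      ", final E = ", signif(x$final_error, 5), " after ",
      nrow(x$trace), " epochs\n", sep = "")
  invisible(x)
}

#' @rdname train_abpnn
#' @param x,object an `abpnn_fit`.
#' @param ... unused.
#' @export
tidy.abpnn_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c(paste0("omega", seq_len(p$q)), paste0("tau", seq_len(p$q)),
             paste0("a", seq_len(p$q), ",1"), paste0("a", seq_len(p$q), ",2"),
             "b1", "b2"),
    estimate = abpnn_flatten(p)
  )
}

#' @rdname train_abpnn
#' @export
glance.abpnn_fit <- function(x, ...) {
  tibble::tibble(q = x$params$q, epochs = nrow(x$trace),
                 init_error = x$init_error, final_error = x$final_error,
                 final_eta = utils::tail(x$trace$eta, 1))
}
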