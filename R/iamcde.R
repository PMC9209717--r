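#' Configuration for the differential-evolution minimizer
#'
#' Three variants are supported.  `"DE"` is classic differential
#' evolution with fixed mutation factor `F` and crossover rate `CR`.
#' `"AMCDE"` replaces both by generation-dependent sine/cosine schedules
#' controlled by `a` and `b`.  `"IAMCDE"` keeps the `CR` schedule but
#' draws mutants from two randomized operators (rand/1 and rand/2)
#' chosen by a generation-dependent probability, and restarts the worst
#' half of the population after `n_failmax` consecutive generations
#' without improvement of the best fitness.
#'
#' @param variant `"IAMCDE"`, `"AMCDE"` or `"DE"`.
#' @param S population size (>= 6; rand/2 needs five distinct members).
#' @param gmax number of generations.
#' @param F fixed mutation factor for classic DE, in `[0, 2]`.
#' @param CR fixed crossover rate for classic DE.
#' @param a,b schedule constants in `[0.5, 1]` for the F and CR schedules.
#' @param pro_min,pro_max bounds of the mutation-operator probability.
#' @param n_failmax consecutive non-improving generations tolerated
#'   before the population-randomization restart (IAMCDE only).
#' @param bounds length-2 numeric, per-dimension search box for
#'   initialization (mutants are not clipped back into it).
#' @param seed optional integer; makes the run bit-reproducible.
#' @return a list of class `de_config`.
#' @export
de_config <- function(variant = c("IAMCDE", "AMCDE", "DE"),
                      S = 30L, gmax = 100L, F = 0.5, CR = 0.9,
                      a = 0.75, b = 0.75, pro_min = 0.1, pro_max = 0.9,
                      n_failmax = 10L, bounds = c(-1, 1), seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(S >= 6, gmax >= 1, F >= 0, F <= 2,
            a >= 0.5, a <= 1, b >= 0.5, b <= 1,
            pro_min >= 0, pro_min <= pro_max, pro_max <= 1,
            n_failmax >= 1, length(bounds) == 2, bounds[1] < bounds[2] ||
              bounds[1] == bounds[2])
  structure(list(variant = variant, S = as.integer(S), gmax = as.integer(gmax),
                 F = F, CR = CR, a = a, b = b,
                 pro_min = pro_min, pro_max = pro_max,
                 n_failmax = as.integer(n_failmax), bounds = bounds,
                 seed = seed),
            class = "de_config")
}

#' @describeIn de_config draw an initial population uniformly in the
#'   search box; returns an `S x dim` matrix.
#' @param config a `de_config`.
#' @param dim problem dimension.
#' @export
de_init_population <- function(config, dim) {
  stopifnot(dim >= 1)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  matrix(lo + stats::runif(config$S * dim) * (hi - lo),
         nrow = config$S, ncol = dim)
}

#' Generation-dependent mutation-factor and crossover-rate schedules
#'
#' Over the first half of the run the value rises along a quarter sine
#' wave from `2a - 1` to `a`; over the second half it falls along a
#' quarter cosine wave from `2a - 1` back up to `a` (the two branches
#' are intentionally evaluated exactly as specified, including the jump
#' at `gmax / 2`).  `CR` uses the same form with constant `b`.
#'
#' @param G current generation (0 to `gmax`).
#' @param gmax maximum generation.
#' @param a,b schedule constants in `[0.5, 1]`.
#' @return named numeric `c(F = , CR = )`.
#' @export
de_schedule_f_cr <- function(G, gmax, a = 0.75, b = 0.75) {
  sched <- function(k) {
    if (G <= gmax / 2) {
      k + (1 - k) * sin(G / gmax * pi - pi / 2)
    } else {
      k - (1 - k) * cos(pi / 2 - G / gmax * pi)
    }
  }
  c(F = sched(a), CR = sched(b))
}

#' @describeIn de_schedule_f_cr linear schedule of the probability of
#'   the rand/2 mutation operator.
#' @param pro_min,pro_max probability bounds.
#' @export
de_mutation_probability <- function(G, gmax, pro_min = 0.1, pro_max = 0.9) {
  stopifnot(G >= 0, G <= gmax)
  pro_min + G * (pro_max - pro_min) / gmax
}

#' Mutation operators
#'
#' `de_mutate_rand1()` is the classic rand/1 mutant
#' `x_r1 + F * (x_r2 - x_r3)` with three distinct random members.
#' `de_mutate_iamcde()` draws a uniform number; below `pro_G` it uses
#' rand/1 with a fresh uniform factor, otherwise rand/2
#' `x_r1 + rand2 * (x_r2 - x_r3) + rand3 * (x_r4 - x_r5)` with five
#' distinct members.  Since `pro_G` rises over the run, the explorative
#' rand/2 operator dominates early generations and the exploitative
#' rand/1 operator dominates late ones.
#'
#' @param pop `S x dim` population matrix.
#' @param F mutation factor.
#' @return a mutant vector of length `dim`.
#' @export
de_mutate_rand1 <- function(pop, F) {
  r <- sample.int(nrow(pop), 3L)
  pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
}

#' @rdname de_mutate_rand1
#' @param pro_G probability of the rand/1 operator this generation.
#' @export
de_mutate_iamcde <- function(pop, pro_G) {
  stopifnot(nrow(pop) >= 6)
  if (stats::runif(1) < pro_G) {
    r <- sample.int(nrow(pop), 3L)
    pop[r[1], ] + stats::runif(1) * (pop[r[2], ] - pop[r[3], ])
  } else {
    r <- sample.int(nrow(pop), 5L)
    pop[r[1], ] + stats::runif(1) * (pop[r[2], ] - pop[r[3], ]) +
      stats::runif(1) * (pop[r[4], ] - pop[r[5], ])
  }
}

#' Binomial crossover
#'
#' Component `j` of the trial vector comes from the mutant when the
#' `j`-th uniform draw is at most `CR`, otherwise from the target.  No
#' component is forced to come from the mutant.
#'
#' @param target,mutant equal-length numeric vectors.
#' @param CR crossover rate.
#' @export
de_crossover <- function(target, mutant, CR) {
  if (length(target) != length(mutant)) {
    rlang::abort("target and mutant have different dimensions",
      class = "pcseg_dim_mismatch")
  }
  take <- stats::runif(length(target)) <= CR
  ifelse(take, mutant, target)
}

#' @describeIn de_crossover greedy selection: the trial replaces the
#'   target only on a strict fitness improvement.
#' @param trial trial vector.
#' @param f_target,f_trial their objective values.
#' @export
de_select <- function(target, trial, f_target, f_trial) {
  if (f_trial < f_target) list(par = trial, value = f_trial, accepted = TRUE)
  else list(par = target, value = f_target, accepted = FALSE)
}

#' Population-randomization restart
#'
#' Sorts the population by fitness, keeps the best half (so the
#' incumbent best is never lost), and replaces the worst `floor(S/2)`
#' members by fresh uniform draws from the search box.  The fresh
#' members carry `NA` fitness and must be evaluated by the caller.
#'
#' @param pop `S x dim` population matrix.
#' @param fitness length-`S` objective values.
#' @param config a [de_config()].
#' @return list with `pop`, `fitness` (NA for fresh members), and
#'   `replaced` (indices of the fresh rows).
#' @export
de_randomize_population <- function(pop, fitness, config) {
  S <- nrow(pop)
  ord <- order(fitness)
  keep <- ord[seq_len(ceiling(S / 2))]
  n_new <- S - length(keep)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  fresh <- matrix(lo + stats::runif(n_new * ncol(pop)) * (hi - lo),
                  nrow = n_new, ncol = ncol(pop))
  new_pop <- rbind(pop[keep, , drop = FALSE], fresh)
  new_fit <- c(fitness[keep], rep(NA_real_, n_new))
  list(pop = new_pop, fitness = new_fit,
       replaced = seq.int(length(keep) + 1L, S))
}

#' Minimize an objective by differential evolution
#'
#' Runs the configured variant for `gmax` generations with elitist
#' selection, tracking the best-so-far solution.  For IAMCDE a
#' generation without strict improvement of the population best
#' increments a failure counter; at `n_failmax` failures the
#' population-randomization restart fires.  With `config$seed` set the
#' run is bit-reproducible and leaves the caller's RNG state untouched.
#'
#' @param objective function mapping a numeric vector of length `dim` to
#'   a finite scalar.
#' @param dim problem dimension.
#' @param config a [de_config()].
#' @return an object of class `de_result`: `par`, `value`, `history`
#'   (best fitness per generation), `n_evals`, `restarts`, `config`.
#' @examples
#' res <- de_minimize(function(x) sum(x^2), 2,
#'                    de_config("IAMCDE", gmax = 50, seed = 1))
#' glance(res)
#' @export
de_minimize <- function(objective, dim, config = de_config()) {
  run <- function() .de_minimize_impl(objective, dim, config)
  res <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  res
}

.de_minimize_impl <- function(objective, dim, config) {
  S <- config$S
  evalf <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) {
      rlang::abort("objective returned a non-finite value",
        class = "pcseg_nonfinite_objective")
    }
    v
  }
  pop <- de_init_population(config, dim)
  fitness <- apply(pop, 1, evalf)
  n_evals <- S
  n_fail <- 0L
  restarts <- 0L
  history <- numeric(config$gmax)
  best_prev <- min(fitness)
  for (G in seq_len(config$gmax)) {
    fcr <- switch(config$variant,
      DE = c(F = config$F, CR = config$CR),
      AMCDE = de_schedule_f_cr(G, config$gmax, config$a, config$b),
      IAMCDE = de_schedule_f_cr(G, config$gmax, config$a, config$b))
    pro_G <- de_mutation_probability(G, config$gmax, config$pro_min, config$pro_max)
    for (s in seq_len(S)) {
      mutant <- if (config$variant == "IAMCDE") {
        de_mutate_iamcde(pop, pro_G)
      } else {
        de_mutate_rand1(pop, fcr[["F"]])
      }
      trial <- de_crossover(pop[s, ], mutant, fcr[["CR"]])
      f_trial <- evalf(trial)
      n_evals <- n_evals + 1L
      sel <- de_select(pop[s, ], trial, fitness[s], f_trial)
      pop[s, ] <- sel$par
      fitness[s] <- sel$value
    }
    best_now <- min(fitness)
    if (best_now < best_prev) n_fail <- 0L else n_fail <- n_fail + 1L
    best_prev <- best_now
    if (config$variant == "IAMCDE" && n_fail >= config$n_failmax) {
      rs <- de_randomize_population(pop, fitness, config)
      pop <- rs$pop
      fitness <- rs$fitness
      fitness[rs$replaced] <- apply(pop[rs$replaced, , drop = FALSE], 1, evalf)
      n_evals <- n_evals + length(rs$replaced)
      n_fail <- 0L
      restarts <- restarts + 1L
      best_prev <- min(best_prev, min(fitness))
    }
    history[G] <- best_prev
  }
  i <- which.min(fitness)
  structure(list(par = pop[i, ], value = fitness[i], history = history,
                 n_evals = n_evals, restarts = restarts, config = config),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", x$config$variant, ": best = ", signif(x$value, 6),
      " after ", length(x$history), " generations (", x$restarts,
      " restarts)\n", sep = "")
  invisible(x)
}

#' @rdname de_minimize
#' @param x,object a `de_result`.
#' @param ... unused.
#' @export
tidy.de_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history), best_fitness = x$history)
}

#' @rdname de_minimize
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(variant = x$config$variant, best_fitness = x$value,
                 generations = length(x$history), n_evals = x$n_evals,
                 restarts = x$restarts)
}
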