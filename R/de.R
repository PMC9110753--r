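#' Differential-evolution optimizer
#'
#' Classic DE/rand/1/bin global minimizer on a box, used for maximum
#' likelihood fitting of the choice models. Deterministic given `seed`;
#' the caller's RNG state is restored afterwards.
#'
#' @param fn Objective function of a numeric vector, returning a scalar.
#' @param lower,upper Numeric bound vectors (equal length, all finite).
#' @param settings A [de_settings()] list.
#' @param seed Integer seed (optional but recommended).
#' @return List with `par`, `value`, `converged` (population collapsed
#'   within tolerance before the generation cap), `n_gen`, `n_evals`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' de_optim(sphere, c(-5, -5), c(5, 5), seed = 1)$value
de_optim <- function(fn, lower, upper, settings = de_settings(), seed = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  np <- if (is.null(settings$n_pop)) 15L * d else as.integer(settings$n_pop)
  np <- max(np, 5L)
  Fw <- settings$F; CR <- settings$CR
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  fit <- apply(pop, 1, fn)
  n_evals <- np
  converged <- FALSE
  gen <- 0L
  for (gen in seq_len(settings$max_gen)) {
    for (i in seq_len(np)) {
      r <- sample.int(np, 3L)
      while (any(r == i)) r <- sample.int(np, 3L)
      mutant <- pop[r[1], ] + Fw * (pop[r[2], ] - pop[r[3], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      f_trial <- fn(trial)
      n_evals <- n_evals + 1L
      if (f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
    spread <- max(fit) - min(fit)
    if (is.finite(spread) && spread <= settings$tol * (abs(min(fit)) + settings$tol)) {
      converged <- TRUE
      break
    }
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], converged = converged,
       n_gen = gen, n_evals = n_evals)
}

#' Optimizer settings for model fitting
#'
#' @param n_pop Population size (`NULL` = 15 x dimension).
#' @param max_gen Generation cap.
#' @param F Differential weight.
#' @param CR Crossover probability.
#' @param tol Relative population-spread tolerance for early convergence.
#' @return List of settings for [de_optim()].
#' @export
de_settings <- function(n_pop = NULL, max_gen = 200L, F = 0.8, CR = 0.9,
                        tol = 1e-6) {
  list(n_pop = n_pop, max_gen = as.integer(max_gen), F = F, CR = CR, tol = tol)
}
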