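#' Sample a spatially correlated reward landscape
#'
#' Draws one environment the way the task generated them: a 165-dimensional
#' (or `grid$n_options`-dimensional) multivariate normal with RBF covariance,
#' then min-max rescaled so rewards run from 0 to a maximum drawn from a
#' discrete uniform distribution on `max_value_range` (default integers
#' 80..120). Observation noise applied at draw time is `N(0, noise_sd^2)`.
#'
#' @param grid A [grid_spec()].
#' @param lambda_ Positive length-scale of the generative RBF kernel
#'   (the experiment used 1.5).
#' @param max_value_range Integer vector of admissible landscape maxima;
#'   one value is sampled uniformly.
#' @param seed Integer seed making the draw reproducible.
#' @param noise_sd Standard deviation of reward observation noise (default 1,
#'   in raw reward points).
#' @param jitter Diagonal jitter added to the covariance before factorization
#'   (numerical positive-definiteness safeguard).
#'
#' @return An object of class `bandit_env`: list with `mean_rewards`
#'   (length `n_options`, min 0, max `max_value`), `max_value`, `lambda`,
#'   `noise_sd`, `seed`, and `grid`.
#' @export
#' @examples
#' env <- sample_environment(grid_spec(), 1.5, seed = 1)
#' range(env$mean_rewards) # 0 .. max_value
sample_environment <- function(grid, lambda_, max_value_range = 80:120,
                               seed = NULL, noise_sd = 1, jitter = 1e-8) {
  if (lambda_ <= 0) stop("lambda_ must be positive")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  K <- kernel_matrix(grid, lambda_) + diag(jitter, grid$n_options)
  L <- tryCatch(chol(K), error = function(e) {
    stop("covariance not positive definite after jitter ", jitter,
         " (lambda_ = ", lambda_, "): ", conditionMessage(e))
  })
  raw <- drop(crossprod(L, stats::rnorm(grid$n_options)))
  max_value <- sample(as.integer(max_value_range), 1L)
  rng <- range(raw)
  mean_rewards <- (raw - rng[1]) / (rng[2] - rng[1]) * max_value
  structure(
    list(mean_rewards = mean_rewards, max_value = max_value,
         lambda = lambda_, noise_sd = noise_sd,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         grid = grid),
    class = "bandit_env"
  )
}

#' @export
print.bandit_env <- function(x, ...) {
  cat(sprintf(
    "<bandit_env> %d options, lambda = %g, max = %d, noise_sd = %g, seed = %s\n",
    length(x$mean_rewards), x$lambda, x$max_value, x$noise_sd,
    ifelse(is.na(x$seed), "<none>", x$seed)))
  invisible(x)
}

#' Sample a set of independent environments for one experiment
#'
#' One master seed spawns one sub-seed per environment, so the set is
#' reproducible as a whole while each landscape is an independent GP draw.
#'
#' @param n_envs Number of environments (a session sequence uses 6).
#' @param grid A [grid_spec()].
#' @param lambda_ Generative length-scale.
#' @param master_seed Integer master seed.
#' @param ... Passed to [sample_environment()].
#' @return List of `bandit_env`, with per-environment `seed` recorded.
#' @export
sample_environment_set <- function(n_envs = 6L, grid = grid_spec(),
                                   lambda_ = 1.5, master_seed = NULL, ...) {
  sub_seeds <- spawn_seeds(master_seed, n_envs)
  lapply(sub_seeds, function(s) sample_environment(grid, lambda_, seed = s, ...))
}

#' Draw a noisy reward from an environment
#'
#' Returns the option's mean reward plus Gaussian observation noise
#' `N(0, noise_sd^2)`; every press of the same option is an independent draw.
#'
#' @param env A `bandit_env`.
#' @param i 0-based option index (vectorized).
#' @param n Number of draws per index element (default 1).
#' @return Numeric vector of raw reward points (not clipped).
#' @export
draw_reward <- function(env, i, n = 1L) {
  check_option_index(env$grid, i)
  m <- rep(env$mean_rewards[i + 1L], each = n)
  m + stats::rnorm(length(m), 0, env$noise_sd)
}

# -- seed plumbing ------------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Spawn reproducible sub-seeds from a master seed
#'
#' @param master_seed Integer master seed (or `NULL` to use the current RNG
#'   stream without reseeding).
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` sub-seeds, each below 2^31.
#' @export
spawn_seeds <- function(master_seed, n) {
  if (!is.null(master_seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(master_seed))
  }
  sample.int(.Machine$integer.max, n)
}
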