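#' Observation set for GP conditioning
#'
#' The running log of one session: which options were chosen and which
#' (scaled) rewards they returned, in trial order. Duplicate choices are
#' kept as separate observations; the observation-noise term in the GP
#' handles the repeats.
#'
#' @param indices Integer vector of 0-based option indices.
#' @param rewards Numeric vector of scaled rewards (same length).
#' @return Object of class `observation_set`.
#' @export
observation_set <- function(indices = integer(0), rewards = numeric(0)) {
  if (length(indices) != length(rewards)) {
    stop("indices and rewards must have equal length")
  }
  if (length(rewards) && any(!is.finite(rewards))) stop("rewards must be finite")
  structure(list(indices = as.integer(indices), rewards = as.numeric(rewards)),
            class = "observation_set")
}

#' Gaussian-process posterior over all options
#'
#' Exact GP regression under a zero-mean prior with unit prior variance and
#' RBF covariance with length-scale `lambda_hat`, conditioned on the
#' observations. Returns the posterior mean `m(x)` and the predictive
#' standard deviation `s(x)` of the latent mean reward at every option, the
#' two quantities the UCB policy consumes.
#'
#' @param obs An [observation_set()] (rewards on the scaled, order-unity
#'   scale; see [scale_rewards()]).
#' @param lambda_hat Positive length-scale of the agent's subjective kernel.
#' @param noise_var Observation-noise variance on the scaled scale
#'   (default `1e-4`, i.e. the generative unit-sd noise after dividing
#'   rewards by 100).
#' @param grid A [grid_spec()].
#' @return Object of class `gp_posterior`: list with `mean` and `sd`
#'   vectors of length `grid$n_options`. With no observations the prior is
#'   returned unchanged (`mean` 0, `sd` 1 everywhere).
#' @export
#' @examples
#' g <- grid_spec(3, 3)
#' post <- gp_posterior(observation_set(4L, 0.8), 1.5, grid = g)
#' which.max(post$mean) - 1L # the observed cell
gp_posterior <- function(obs, lambda_hat, noise_var = 1e-4, grid = grid_spec()) {
  if (lambda_hat <= 0) stop("lambda_hat must be positive")
  if (noise_var <= 0) stop("noise_var must be positive")
  n <- grid$n_options
  t_obs <- length(obs$indices)
  if (t_obs == 0L) {
    return(structure(list(mean = rep(0, n), sd = rep(1, n)),
                     class = "gp_posterior"))
  }
  check_option_index(grid, obs$indices)
  K <- kernel_matrix(grid, lambda_hat)
  gp_posterior_from_K(K, obs$indices, obs$rewards, noise_var)
}

# Core conditioning step on a precomputed kernel matrix; used by the
# simulation loop so K is built once per (session, lambda_hat).
gp_posterior_from_K <- function(K, indices, rewards, noise_var) {
  t_obs <- length(indices)
  if (t_obs == 0L) {
    return(structure(list(mean = rep(0, nrow(K)), sd = rep(1, nrow(K))),
                     class = "gp_posterior"))
  }
  io <- indices + 1L
  K_oo <- K[io, io, drop = FALSE] + diag(noise_var, t_obs)
  K_so <- K[, io, drop = FALSE]                      # n x t
  L <- tryCatch(chol(K_oo), error = function(e) {
    stop("Gram matrix singular despite noise term (condition estimate ",
         format(kappa(K_oo)), "): ", conditionMessage(e))
  })
  # m = K_so (K_oo)^-1 y ; s^2 = 1 - diag(K_so (K_oo)^-1 K_os)
  alpha <- backsolve(L, backsolve(L, rewards, transpose = TRUE))
  m <- drop(K_so %*% alpha)
  V <- backsolve(L, t(K_so), transpose = TRUE)       # t x n
  s2 <- pmax(1 - colSums(V^2), 0)
  structure(list(mean = m, sd = sqrt(s2)), class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> %d options; mean in [%.3f, %.3f], sd in [%.3f, %.3f]\n",
              length(x$mean), min(x$mean), max(x$mean), min(x$sd), max(x$sd)))
  invisible(x)
}

#' Scale raw point rewards for GP conditioning
#'
#' Raw rewards (0..~120 points) are divided by 100 to sit on the GP's
#' unit-variance prior scale; [unscale_rewards()] inverts exactly.
#'
#' @param raw_rewards Numeric vector of raw point rewards.
#' @return Scaled rewards.
#' @export
scale_rewards <- function(raw_rewards) {
  if (any(!is.finite(raw_rewards))) stop("rewards must be finite")
  raw_rewards / 100
}

#' @rdname scale_rewards
#' @param scaled_rewards Numeric vector of scaled rewards.
#' @export
unscale_rewards <- function(scaled_rewards) scaled_rewards * 100
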