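#' Parameter-recovery study
#'
#' Samples agent parameter vectors, simulates full experiments (fresh
#' 6-environment sets per pair), refits each simulated agent by maximum
#' likelihood, and cross-correlates generating with recovered parameters.
#' Good recovery shows high diagonal correlations (each parameter recovers
#' itself) and low off-diagonal ones (parameters do not masquerade as each
#' other).
#'
#' @param n_agents Number of simulated agents (rounded up to an even count
#'   in the pair condition; at least 10 for correlation stability).
#' @param param_sampler Function of `condition` returning [agent_params()]
#'   (default [default_param_sampler()]).
#' @param condition `"pair"` (default; fits the full UCB+S model, 4
#'   parameters) or `"solo"` (fits the UCB model, 3 parameters).
#' @param bounds,settings,noise_var Passed to [fit_participant()].
#' @param n_envs,n_trials Experiment size per agent (default 6 x 25).
#' @param env_lambda Generative length-scale of the landscapes.
#' @param grid A [grid_spec()].
#' @param master_seed Integer master seed; all sub-seeds derive from it.
#' @return Object of class `recovery_report`: list with `generating` and
#'   `recovered` matrices (agents x parameters), `corr_matrix` (Pearson,
#'   generating rows vs recovered columns), `diag`, `offdiag_max_abs`,
#'   `corr_matrix_spearman`, `n_agents`, `n_failed`.
#' @export
run_recovery <- function(n_agents = 30L, param_sampler = default_param_sampler,
                         condition = c("pair", "solo"),
                         bounds = default_bounds(), settings = de_settings(),
                         n_envs = 6L, n_trials = 25L, env_lambda = 1.5,
                         grid = grid_spec(), master_seed = NULL,
                         noise_var = 1e-4) {
  condition <- match.arg(condition)
  if (n_agents < 10L) stop("n_agents must be at least 10 for stable correlations")
  param_names <- if (condition == "pair") {
    c("lambda_hat", "beta", "gamma", "tau")
  } else {
    c("lambda_hat", "beta", "tau")
  }
  spec <- model_spec(use_uncertainty = TRUE,
                     use_social = condition == "pair",
                     name = if (condition == "pair") "UCB+S" else "UCB")
  if (condition == "pair" && n_agents %% 2L == 1L) n_agents <- n_agents + 1L
  n_units <- if (condition == "pair") n_agents %/% 2L else n_agents
  seeds <- matrix(spawn_seeds(master_seed, 5L * n_units), nrow = n_units)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)

  agents <- list()
  for (u in seq_len(n_units)) {
    envs <- sample_environment_set(n_envs, grid, env_lambda,
                                   master_seed = seeds[u, 1])
    set.seed(seeds[u, 2])
    if (condition == "pair") {
      pa <- param_sampler("pair")
      pb <- param_sampler("pair")
      pair <- simulate_pair(pa, pb, envs, n_trials, seed = seeds[u, 3],
                            pair_id = sprintf("recpair_%03d", u),
                            noise_var = noise_var)
      agents[[length(agents) + 1L]] <- list(data = pair$a, seed = seeds[u, 4])
      agents[[length(agents) + 1L]] <- list(data = pair$b, seed = seeds[u, 5])
    } else {
      p <- param_sampler("solo")
      pd <- simulate_solo(p, envs, n_trials, seed = seeds[u, 3],
                          participant_id = sprintf("recsolo_%03d", u),
                          noise_var = noise_var)
      agents[[length(agents) + 1L]] <- list(data = pd, seed = seeds[u, 4])
    }
  }

  gen <- matrix(NA_real_, length(agents), length(param_names),
                dimnames = list(NULL, param_names))
  rec <- gen
  failed <- 0L
  for (i in seq_along(agents)) {
    a <- agents[[i]]
    gen[i, ] <- unlist(a$data$true_params[param_names])
    fit <- tryCatch(
      fit_participant(a$data, spec, bounds, settings, seed = a$seed,
                      noise_var = noise_var),
      error = function(e) NULL
    )
    if (is.null(fit)) { failed <- failed + 1L; next }
    rec[i, ] <- unlist(fit$params[param_names])
  }
  ok <- stats::complete.cases(rec)
  gen <- gen[ok, , drop = FALSE]
  rec <- rec[ok, , drop = FALSE]
  cm <- stats::cor(gen, rec, method = "pearson")
  cs <- stats::cor(gen, rec, method = "spearman")
  off <- abs(cm)
  diag(off) <- 0
  structure(
    list(generating = gen, recovered = rec, corr_matrix = cm,
         diag = diag(cm), offdiag_max_abs = max(off),
         corr_matrix_spearman = cs, n_agents = nrow(gen), n_failed = failed,
         condition = condition),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d %s-condition agents (%d failed fits)\n",
              x$n_agents, x$condition, x$n_failed))
  cat("generating-vs-recovered Pearson correlations:\n")
  print(round(x$corr_matrix, 3))
  cat(sprintf("diagonal: %s; max |off-diagonal| = %.3f\n",
              paste(sprintf("%.2f", x$diag), collapse = ", "),
              x$offdiag_max_abs))
  invisible(x)
}
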