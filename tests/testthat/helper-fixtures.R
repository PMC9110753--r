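# Shared fixtures: small grids, quick environments and a hand-rolled
# joint-Gaussian conditioning oracle used to validate the GP machinery.

tiny_grid <- function(nr = 3, nc = 3) grid_spec(nr, nc)

quick_envs <- function(n = 2, seed = 123, grid = grid_spec()) {
  sample_environment_set(n, grid, 1.5, master_seed = seed)
}

# Brute-force GP oracle: condition the joint multivariate normal
# [f(all options); y(observed)] directly. Independent of the package's
# Cholesky-based regression path.
brute_force_posterior <- function(indices, rewards, lambda_, noise_var, grid) {
  n <- grid$n_options
  Kff <- outer(seq_len(n), seq_len(n), function(a, b) {
    rbf_kernel(a - 1L, b - 1L, lambda_, grid)
  })
  io <- indices + 1L
  Kyy <- Kff[io, io, drop = FALSE] + diag(noise_var, length(io))
  Kfy <- Kff[, io, drop = FALSE]
  Kyy_inv <- solve(Kyy)
  m <- drop(Kfy %*% Kyy_inv %*% rewards)
  S <- Kff - Kfy %*% Kyy_inv %*% t(Kfy)
  list(mean = m, sd = sqrt(pmax(diag(S), 0)))
}

# A tiny deterministic participant log for likelihood tests.
toy_participant <- function(grid = grid_spec(2, 2), condition = "solo",
                            choices = c(0L, 3L, 1L),
                            rewards = c(40, 70, 55),
                            partner = c(NA, 2L, 0L)) {
  if (condition == "solo") partner <- rep(NA_integer_, length(choices))
  participant_data(
    "toy", condition, pair_id = if (condition == "pair") "tp" else NA,
    records = data.frame(session = 1L, trial = seq_along(choices),
                         choice = choices, reward = rewards,
                         partner_prev_choice = partner),
    grid = grid
  )
}
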