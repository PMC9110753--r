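#' Participant trial log
#'
#' Container for one participant's full record: 25-trial sessions on a
#' sequence of environments, with the partner's previous-trial choice
#' attached in the pair condition. Synthetic participants also carry the
#' generating parameters and the environment set.
#'
#' @param participant_id Identifier string.
#' @param condition `"solo"` or `"pair"`.
#' @param pair_id Pair identifier or `NA` (solo).
#' @param records data.frame with columns `session`, `trial`, `choice`
#'   (0-based option index), `reward` (raw points), `partner_prev_choice`
#'   (0-based index or `NA`), and optionally `prob` (the model probability
#'   of the chosen option at simulation time).
#' @param true_params Generating [agent_params()] (synthetic data only).
#' @param envs Environment list, indexed by session, when known.
#' @param grid A [grid_spec()].
#' @return Object of class `participant_data`.
#' @export
participant_data <- function(participant_id, condition, pair_id = NA,
                             records, true_params = NULL, envs = NULL,
                             grid = grid_spec()) {
  condition <- match.arg(condition, c("solo", "pair"))
  req <- c("session", "trial", "choice", "reward", "partner_prev_choice")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(records$reward))) stop("rewards must be finite")
  check_option_index(grid, records$choice)
  pp <- records$partner_prev_choice
  if (condition == "solo" && any(!is.na(pp))) {
    stop("solo-condition records must not carry partner cues")
  }
  if (any(records$trial == 1L & !is.na(pp))) {
    stop("trial-1 records cannot carry a partner cue (no preceding trial)")
  }
  if (any(!is.na(pp))) check_option_index(grid, pp[!is.na(pp)])
  structure(
    list(participant_id = as.character(participant_id), condition = condition,
         pair_id = pair_id, records = records, true_params = true_params,
         envs = envs, grid = grid),
    class = "participant_data"
  )
}

#' @export
print.participant_data <- function(x, ...) {
  cat(sprintf("<participant_data> %s (%s%s): %d sessions, %d trials\n",
              x$participant_id, x$condition,
              if (!is.na(x$pair_id)) paste0(", pair ", x$pair_id) else "",
              length(unique(x$records$session)), nrow(x$records)))
  invisible(x)
}

# One agent's single-session loop. Beliefs start from the prior; each trial
# computes the posterior, values, softmax probabilities, samples a choice and
# draws a noisy reward. RNG draws happen in a fixed order (choice, then
# reward noise) so seeded runs are reproducible.
simulate_session_step <- function(state, env, params, spec, partner_prev,
                                  noise_var, K) {
  post <- gp_posterior_from_K(K, state$indices, state$rewards_scaled, noise_var)
  vv <- total_values(post, params, spec, partner_index = partner_prev,
                     grid = env$grid, solo = FALSE)
  probs <- softmax_probs(vv, params$tau)$probs
  choice <- sample.int(env$grid$n_options, 1L, prob = probs) - 1L
  reward <- env$mean_rewards[choice + 1L] + stats::rnorm(1, 0, env$noise_sd)
  state$indices <- c(state$indices, choice)
  state$rewards_scaled <- c(state$rewards_scaled, scale_rewards(reward))
  state$choice <- choice
  state$reward <- reward
  state$prob <- probs[choice + 1L]
  state
}

#' Simulate a solo searcher
#'
#' One agent works through the environment sequence, 25 trials per session
#' (configurable), resetting GP beliefs at each session boundary. No social
#' term enters the valuation.
#'
#' @param params An [agent_params()] (`gamma` is ignored).
#' @param envs List of `bandit_env` (one per session; the task used 6).
#' @param n_trials Trials per session (default 25).
#' @param seed Integer seed (optional).
#' @param noise_var GP observation-noise variance on the scaled scale.
#' @param participant_id,pair_id Identifiers stored in the result.
#' @return A [participant_data()] with `6 x 25` records under defaults.
#' @export
simulate_solo <- function(params, envs, n_trials = 25L, seed = NULL,
                          noise_var = 1e-4, participant_id = "solo_1",
                          pair_id = NA) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  grid <- envs[[1]]$grid
  spec <- model_spec(use_uncertainty = TRUE, use_social = FALSE, name = "sim-solo")
  K <- kernel_matrix(grid, params$lambda_hat)
  rows <- vector("list", length(envs))
  for (s in seq_along(envs)) {
    state <- list(indices = integer(0), rewards_scaled = numeric(0))
    rec <- data.frame(session = rep(s, n_trials), trial = seq_len(n_trials),
                      choice = NA_integer_, reward = NA_real_,
                      partner_prev_choice = NA_integer_, prob = NA_real_)
    for (t in seq_len(n_trials)) {
      state <- simulate_session_step(state, envs[[s]], params, spec, NULL,
                                     noise_var, K)
      rec$choice[t] <- state$choice
      rec$reward[t] <- state$reward
      rec$prob[t] <- state$prob
    }
    rows[[s]] <- rec
  }
  participant_data(participant_id, "solo", pair_id, do.call(rbind, rows),
                   true_params = params, envs = envs, grid = grid)
}

#' Simulate an interacting pair
#'
#' Both agents choose simultaneously on every trial; from trial 2 onward
#' each sees the location (only) of the partner's previous choice, which
#' enters their valuation as the kernel-shaped imitation bonus. Rewards are
#' drawn independently and GP beliefs are private. Each agent runs on its
#' own RNG substream, so a pair with `gamma = 0` reproduces two independent
#' solo runs draw-for-draw.
#'
#' @param params_a,params_b [agent_params()] for the two agents.
#' @param envs Shared environment list (one per session).
#' @param n_trials Trials per session (default 25).
#' @param seed Master seed; spawns one substream per agent.
#' @param noise_var GP observation-noise variance on the scaled scale.
#' @param pair_id Identifier stored on both members.
#' @param participant_ids Length-2 identifiers.
#' @return List of two [participant_data()] objects.
#' @export
simulate_pair <- function(params_a, params_b, envs, n_trials = 25L,
                          seed = NULL, noise_var = 1e-4, pair_id = "pair_1",
                          participant_ids = paste0(pair_id, c("_a", "_b"))) {
  sub <- spawn_seeds(seed, 2L)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  grid <- envs[[1]]$grid
  spec <- model_spec(use_uncertainty = TRUE, use_social = TRUE, name = "sim-pair")
  params <- list(params_a, params_b)
  K <- lapply(params, function(p) kernel_matrix(grid, p$lambda_hat))
  # independent RNG substreams per agent
  rng <- lapply(sub, function(s) { set.seed(s); get_rng_state() })
  recs <- lapply(1:2, function(a) vector("list", length(envs)))
  for (s in seq_along(envs)) {
    states <- list(list(indices = integer(0), rewards_scaled = numeric(0)),
                   list(indices = integer(0), rewards_scaled = numeric(0)))
    rec <- data.frame(session = rep(s, n_trials), trial = seq_len(n_trials),
                      choice = NA_integer_, reward = NA_real_,
                      partner_prev_choice = NA_integer_, prob = NA_real_)
    rec <- list(rec, rec)
    prev_choice <- c(NA_integer_, NA_integer_)
    for (t in seq_len(n_trials)) {
      new_choice <- prev_choice
      for (a in 1:2) {
        partner <- if (t == 1L) NULL else prev_choice[3L - a]
        set_rng_state(rng[[a]])
        states[[a]] <- simulate_session_step(states[[a]], envs[[s]],
                                             params[[a]], spec, partner,
                                             noise_var, K[[a]])
        rng[[a]] <- get_rng_state()
        rec[[a]]$choice[t] <- states[[a]]$choice
        rec[[a]]$reward[t] <- states[[a]]$reward
        rec[[a]]$prob[t] <- states[[a]]$prob
        rec[[a]]$partner_prev_choice[t] <- if (t == 1L) NA_integer_ else prev_choice[3L - a]
        new_choice[a] <- states[[a]]$choice
      }
      prev_choice <- new_choice
    }
    for (a in 1:2) recs[[a]][[s]] <- rec[[a]]
  }
  out <- lapply(1:2, function(a) {
    participant_data(participant_ids[a], "pair", pair_id,
                     do.call(rbind, recs[[a]]),
                     true_params = params[[a]], envs = envs, grid = grid)
  })
  names(out) <- c("a", "b")
  out
}

#' Imitation-bias performance sweep
#'
#' Simulates pairs whose members share one parameter vector, varying the
#' imitation bias `gamma` over a grid while the other parameters stay fixed,
#' and reports mean per-trial raw reward per `gamma`. Each replicate is one
#' freshly sampled landscape searched for `n_trials` trials (sessions are
#' belief-independent, so replicating single sessions is equivalent to
#' replicating multi-session runs).
#'
#' @param gamma_grid Non-negative `gamma` values to test.
#' @param fixed_params [agent_params()] supplying `lambda_hat`, `beta`,
#'   `tau` (its `gamma` is overwritten per grid point).
#' @param n_replicates Pair replicates per grid point (default 200).
#' @param n_trials Trials per replicate session.
#' @param env_lambda Generative length-scale of the sampled landscapes.
#' @param grid A [grid_spec()].
#' @param master_seed Integer master seed.
#' @return data.frame with one row per `gamma`: mean, sd and standard error
#'   of per-trial reward, plus replicate count.
#' @export
gamma_sweep <- function(gamma_grid, fixed_params, n_replicates = 200L,
                        n_trials = 25L, env_lambda = 1.5, grid = grid_spec(),
                        master_seed = NULL) {
  if (length(gamma_grid) == 0L) stop("gamma_grid must be non-empty")
  if (any(gamma_grid < 0)) stop("gamma values must be non-negative")
  seeds <- matrix(spawn_seeds(master_seed, 2L * length(gamma_grid) * n_replicates),
                  nrow = length(gamma_grid))
  out <- lapply(seq_along(gamma_grid), function(gi) {
    g <- gamma_grid[gi]
    p <- agent_params(fixed_params$lambda_hat, fixed_params$beta, g,
                      fixed_params$tau)
    perf <- vapply(seq_len(n_replicates), function(r) {
      env <- sample_environment(grid, env_lambda, seed = seeds[gi, 2L * r - 1L])
      pair <- simulate_pair(p, p, list(env), n_trials = n_trials,
                            seed = seeds[gi, 2L * r])
      mean(c(pair$a$records$reward, pair$b$records$reward))
    }, numeric(1))
    data.frame(gamma = g, mean_performance = mean(perf),
               sd_performance = stats::sd(perf),
               se_performance = stats::sd(perf) / sqrt(n_replicates),
               n_replicates = n_replicates)
  })
  do.call(rbind, out)
}

#' Default parameter sampler for synthetic cohorts
#'
#' Draws `lambda_hat ~ U[0.5, 4]`, `beta ~ U[0, 1]`, `tau ~ U[0.005, 0.2]`,
#' and `gamma ~ U[0, 1]` in the pair condition (0 for solo agents, whose
#' model has no social term). The ranges bracket the empirical medians of
#' the fitted model while exercising the fitting bounds.
#'
#' @param condition `"solo"` or `"pair"`.
#' @return An [agent_params()].
#' @export
default_param_sampler <- function(condition = "pair") {
  agent_params(
    lambda_hat = stats::runif(1, 0.5, 4),
    beta = stats::runif(1, 0, 1),
    gamma = if (condition == "pair") stats::runif(1, 0, 1) else 0,
    tau = stats::runif(1, 0.005, 0.2)
  )
}

#' Generate a full synthetic cohort
#'
#' Emulates the experiment's cohort structure: `n_solo` solo participants
#' and `n_pairs` interacting pairs, each participant/pair on a fresh
#' 6-environment set sampled from the generative GP prior. Generating
#' parameters are stored on every participant for recovery testing.
#'
#' @param n_solo Number of solo participants (experiment: 47).
#' @param n_pairs Number of pairs (experiment: 37).
#' @param param_sampler Function of `condition` returning [agent_params()].
#' @param master_seed Integer master seed.
#' @param n_envs Environments (sessions) per participant/pair.
#' @param n_trials Trials per session.
#' @param env_lambda Generative length-scale.
#' @param grid A [grid_spec()].
#' @param n_truncated Number of solo participants whose logs keep only the
#'   first 3 sessions (emulating the experiment's 3 truncated participants).
#' @return List of [participant_data()] (length `n_solo + 2 * n_pairs`).
#' @export
generate_synthetic_cohort <- function(n_solo = 47L, n_pairs = 37L,
                                      param_sampler = default_param_sampler,
                                      master_seed = NULL, n_envs = 6L,
                                      n_trials = 25L, env_lambda = 1.5,
                                      grid = grid_spec(), n_truncated = 0L) {
  seeds <- spawn_seeds(master_seed, 3L * (n_solo + n_pairs))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  cohort <- list()
  for (i in seq_len(n_solo)) {
    envs <- sample_environment_set(n_envs, grid, env_lambda, master_seed = nxt())
    set.seed(nxt())
    p <- param_sampler("solo")
    pd <- simulate_solo(p, envs, n_trials, seed = nxt(),
                        participant_id = sprintf("solo_%02d", i))
    if (i <= n_truncated && n_envs > 3L) {
      pd$records <- pd$records[pd$records$session <= 3L, , drop = FALSE]
      pd$envs <- pd$envs[1:3]
    }
    cohort[[length(cohort) + 1L]] <- pd
  }
  for (i in seq_len(n_pairs)) {
    envs <- sample_environment_set(n_envs, grid, env_lambda, master_seed = nxt())
    set.seed(nxt())
    pa <- param_sampler("pair")
    pb <- param_sampler("pair")
    pair <- simulate_pair(pa, pb, envs, n_trials, seed = nxt(),
                          pair_id = sprintf("pair_%02d", i))
    cohort[[length(cohort) + 1L]] <- pair$a
    cohort[[length(cohort) + 1L]] <- pair$b
  }
  cohort
}
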