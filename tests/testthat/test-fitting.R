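test_that("degenerate flat-value model gives the exact uniform likelihood", {
  # all rewards zero => posterior mean identically zero; beta = gamma = 0
  # => every option value is 0 on every trial => exactly uniform softmax
  g <- grid_spec()
  set.seed(8)
  records <- data.frame(session = rep(1:6, each = 25), trial = rep(1:25, 6),
                        choice = sample(0:164, 150, replace = TRUE),
                        reward = 0, partner_prev_choice = NA_integer_)
  pd <- participant_data("u", "solo", records = records, grid = g)
  p <- agent_params(1.5, beta = 0, gamma = 0, tau = 1e6)
  nll <- negative_log_likelihood(pd, p, model_spec(FALSE, FALSE))
  expect_equal(nll, 150 * log(165), tolerance = 1e-9)
})

test_that("negative log likelihood is non-negative", {
  envs <- quick_envs(2)
  p <- agent_params(1.3, 0.6, 0.2, 0.04)
  pair <- simulate_pair(p, p, envs, seed = 4)
  expect_gte(negative_log_likelihood(pair$a, p, model_spec(TRUE, TRUE)), 0)
  expect_gte(negative_log_likelihood(pair$a,
                                     agent_params(3, 0.1, 0.9, 0.5),
                                     model_spec(TRUE, TRUE)), 0)
})

test_that("three-trial toy log matches a hand-composed likelihood", {
  g <- grid_spec(2, 2)
  pd <- toy_participant(g, "pair")
  p <- agent_params(0.8, beta = 0.4, gamma = 0.25, tau = 0.07)
  noise_var <- 1e-4
  # independent composition: brute-force joint-Gaussian conditioning plus
  # explicit softmax terms, multiplied trial by trial
  manual_nll <- 0
  idx <- integer(0); y <- numeric(0)
  r <- pd$records
  for (t in 1:3) {
    if (length(idx) == 0) {
      m <- rep(0, 4); s <- rep(1, 4)
    } else {
      o <- brute_force_posterior(idx, y, p$lambda_hat, noise_var, g)
      m <- o$mean; s <- o$sd
    }
    soc <- if (is.na(r$partner_prev_choice[t])) rep(0, 4) else {
      vapply(0:3, function(i) rbf_kernel(i, r$partner_prev_choice[t],
                                         p$lambda_hat, g), numeric(1))
    }
    v <- (m + p$beta * s + p$gamma * soc) / p$tau
    prob <- exp(v)[r$choice[t] + 1] / sum(exp(v))
    manual_nll <- manual_nll - log(prob)
    idx <- c(idx, r$choice[t]); y <- c(y, scale_rewards(r$reward[t]))
  }
  nll <- negative_log_likelihood(pd, p, model_spec(TRUE, TRUE),
                                 noise_var = noise_var)
  expect_equal(nll, manual_nll, tolerance = 1e-10)
})

test_that("simulation-recorded choice probabilities replay exactly", {
  envs <- quick_envs(3)
  p <- agent_params(1.7, 0.45, 0.3, 0.025)
  pair <- simulate_pair(p, p, envs, seed = 19)
  for (pd in pair) {
    lp <- trial_log_probs(pd, p, model_spec(TRUE, TRUE))
    expect_equal(lp, log(pd$records$prob), tolerance = 1e-10)
  }
  solo <- simulate_solo(p, envs, seed = 23)
  lp <- trial_log_probs(solo, p, model_spec(TRUE, FALSE))
  expect_equal(lp, log(solo$records$prob), tolerance = 1e-10)
})

test_that("gamma = 0 makes the social model's likelihood equal the UCB one", {
  envs <- quick_envs(2)
  p <- agent_params(1.4, 0.5, 0.3, 0.03)
  pair <- simulate_pair(p, p, envs, seed = 41)
  p0 <- agent_params(1.4, 0.5, 0, 0.03)
  expect_equal(
    negative_log_likelihood(pair$a, p0, model_spec(TRUE, TRUE)),
    negative_log_likelihood(pair$a, p0, model_spec(TRUE, FALSE)),
    tolerance = 1e-12
  )
})

test_that("AIC identity holds exactly", {
  expect_equal(aic(-100, 4), 208)
  expect_equal(aic(-50, 0), 100)
  # nested-model algebra
  expect_equal(aic(-80, 4) - aic(-82, 3), -2 * (-80 - (-82)) + 2)
  expect_error(aic(-1, -1), "non-negative")
  envs <- quick_envs(1)
  p <- agent_params(1.5, 0.5, 0, 0.05)
  pd <- simulate_solo(p, envs, seed = 3)
  f <- fit_participant(pd, model_spec(TRUE, FALSE),
                       settings = de_settings(n_pop = 8, max_gen = 5),
                       seed = 2)
  expect_equal(f$aic, -2 * f$log_lik + 2 * f$k)
  expect_lte(f$log_lik, 0)
})

test_that("fitting is deterministic given the optimizer seed", {
  envs <- quick_envs(1)
  p <- agent_params(1.5, 0.5, 0, 0.05)
  pd <- simulate_solo(p, envs, seed = 3)
  st <- de_settings(n_pop = 10, max_gen = 8)
  f1 <- fit_participant(pd, model_spec(TRUE, FALSE), settings = st, seed = 99)
  f2 <- fit_participant(pd, model_spec(TRUE, FALSE), settings = st, seed = 99)
  expect_identical(f1[c("params", "log_lik", "aic", "n_evals")],
                   f2[c("params", "log_lik", "aic", "n_evals")])
})

test_that("the optimizer reaches at least the generating parameters' fit", {
  envs <- quick_envs(6, seed = 77)
  p <- agent_params(1.8, 0.5, 0.25, 0.03)
  pair <- simulate_pair(p, p, envs, seed = 7)
  spec <- model_spec(TRUE, TRUE)
  f <- fit_participant(pair$a, spec,
                       settings = de_settings(n_pop = 24, max_gen = 100,
                                              tol = 1e-5), seed = 5)
  expect_lte(-f$log_lik, negative_log_likelihood(pair$a, p, spec) + 1e-6)
})

test_that("social models refuse solo data", {
  envs <- quick_envs(1)
  pd <- simulate_solo(agent_params(1.5, 0.5, 0, 0.05), envs, seed = 3)
  expect_error(negative_log_likelihood(pd, agent_params(1.5, 0.5, 0.2, 0.05),
                                       model_spec(TRUE, TRUE)), "solo")
  expect_error(fit_participant(pd, model_spec(TRUE, TRUE), seed = 1), "solo")
})
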