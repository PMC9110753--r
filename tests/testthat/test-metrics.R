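make_log <- function(choices, rewards = NULL, sessions = NULL,
                     grid = grid_spec()) {
  n <- length(choices)
  if (is.null(rewards)) rewards <- rep(50, n)
  if (is.null(sessions)) sessions <- rep(1L, n)
  trials <- stats::ave(seq_len(n), sessions, FUN = seq_along)
  participant_data("m", "solo", records = data.frame(
    session = sessions, trial = trials, choice = choices, reward = rewards,
    partner_prev_choice = NA_integer_), grid = grid)
}

test_that("performance summary reduces to means by session and trial", {
  pd <- make_log(rep(0L, 4), rewards = c(10, 20, 30, 40),
                 sessions = c(1L, 1L, 2L, 2L))
  s <- performance_summary(pd)
  expect_equal(s$per_session$mean_reward, c(15, 35))
  expect_equal(s$overall, 25)
  expect_equal(sum(s$per_session$mean_reward * s$per_session$n_trials) /
                 sum(s$per_session$n_trials), s$overall)
  const <- performance_summary(make_log(rep(3L, 5), rewards = rep(7, 5)))
  expect_true(all(const$per_session$mean_reward == 7))
})

test_that("unique choices are first-in-session occurrences, by phase", {
  # all 25 distinct
  pd <- make_log(0:24, sessions = rep(1L, 25))
  u <- unique_choice_proportions(pd)
  expect_equal(u$proportion, c(1, 1, 1))
  # one option pressed all session: only trial 1 is new
  pd2 <- make_log(rep(9L, 25))
  u2 <- unique_choice_proportions(pd2)
  expect_equal(u2$proportion, c(1 / 8, 0, 0))
  # hand-counted repeats: new at trials 1,2,3,9,10,17; repeats elsewhere
  ch <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L,   # phase 1: 3 new
          3L, 4L, 3L, 4L, 3L, 4L, 0L, 1L,   # phase 2: 2 new
          5L, 5L, 5L, 0L, 1L, 2L, 3L, 4L, 5L) # phase 3: 1 new
  u3 <- unique_choice_proportions(make_log(ch))
  expect_equal(u3$n_unique, c(3, 2, 1))
  expect_equal(u3$proportion, c(3 / 8, 2 / 8, 1 / 9))
  # phase unique counts sum to distinct options visited
  expect_equal(sum(u3$n_unique), length(unique(ch)))
  expect_error(phase_definition(list(1:8, 9:16, 17:24)), "partition")
})

test_that("migration length is the mean step distance", {
  g <- grid_spec()
  expect_equal(migration_length(make_log(c(5L, 5L, 5L)))$mean_migration, 0)
  # horizontal neighbours every trial
  expect_equal(migration_length(make_log(c(0L, 1L, 2L, 3L)))$mean_migration, 1)
  # hand-computed path: (0,0) -> (1,1) -> (1,4) -> (0,4)
  path <- c(option_index(g, 0, 0), option_index(g, 1, 1),
            option_index(g, 1, 4), option_index(g, 0, 4))
  expect_equal(migration_length(make_log(path))$mean_migration,
               (sqrt(2) + 3 + 1) / 3)
})

test_that("optimum detection flags sessions containing the argmax", {
  g <- grid_spec()
  env <- sample_environment(g, 1.5, seed = 6)
  best <- which.max(env$mean_rewards) - 1L
  hit <- make_log(c(0L, best, 2L))
  hit$envs <- list(env)
  miss <- make_log(setdiff(0:164, best)[1:3])
  miss$envs <- list(env)
  expect_true(optimum_found(hit)$per_session$found)
  expect_false(optimum_found(miss)$per_session$found)
  expect_equal(optimum_found(hit)$proportion, 1)
})

test_that("prediction accuracy is the mean absolute deviation", {
  truth <- stats::runif(16, 0, 100)
  expect_equal(prediction_accuracy(truth, truth), 0)
  expect_equal(prediction_accuracy(truth + 3.5, truth), 3.5)
  est <- c(10, 20, 30); tr <- c(12, 17, 31)
  expect_equal(prediction_accuracy(est, tr), mean(c(2, 3, 1)))
  expect_error(prediction_accuracy(1:3, 1:4), "equal length")
})

test_that("pair convergence separates a shared parameter from independent ones", {
  set.seed(14)
  n_pairs <- 20
  lam <- stats::runif(n_pairs, 0.5, 4)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    for (m in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = sprintf("p%02d_%d", i, m), condition = "pair",
        pair_id = sprintf("pr%02d", i),
        # partners share lambda_hat within +-10%; beta, gamma, tau independent
        lambda_hat = lam[i] * stats::runif(1, 0.9, 1.1),
        beta = stats::runif(1, 0, 1), gamma = stats::runif(1, 0, 1),
        tau = stats::runif(1, 0.005, 0.2))
    }
  }
  for (i in 1:10) {
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = sprintf("s%02d", i), condition = "solo",
      pair_id = NA_character_, lambda_hat = stats::runif(1, 0.5, 4),
      beta = stats::runif(1, 0, 1), gamma = 0,
      tau = stats::runif(1, 0.005, 0.2))
  }
  fits <- do.call(rbind, rows)
  pc <- pair_convergence(fits, n_shuffles = 200, seed = 8)
  d <- pc$differences
  # no shuffled pairing reproduces a true pairing (guaranteed by construction,
  # visible as strictly positive shuffled lambda differences on average)
  expect_true(all(c("real", "shuffled", "nominal") %in% d$pairing))
  wl <- stats::wilcox.test(
    d$abs_difference[d$pairing == "real" & d$parameter == "lambda_hat"],
    d$abs_difference[d$pairing == "shuffled" & d$parameter == "lambda_hat"],
    alternative = "less")
  expect_lt(wl$p.value, 0.05)
  wb <- stats::wilcox.test(
    d$abs_difference[d$pairing == "real" & d$parameter == "beta"],
    d$abs_difference[d$pairing == "shuffled" & d$parameter == "beta"],
    alternative = "less")
  expect_gt(wb$p.value, 0.05)
  # shared parameter correlates across real pairs
  rho <- pc$correlations
  expect_gt(rho$rho[rho$parameter == "lambda_hat"], 0.5)
  # identical members give zero differences
  two <- fits[fits$pair_id %in% c("pr01", "pr02") & !is.na(fits$pair_id), ]
  two[two$pair_id == "pr01", c("lambda_hat", "beta", "gamma", "tau")] <-
    rep(c(1, 2, 3, 0.1), each = 2)
  pc2 <- pair_convergence(two, n_shuffles = 10, seed = 2)
  real1 <- pc2$differences[pc2$differences$pairing == "real", ]
  expect_true(all(real1$abs_difference[1:4] == 0))
})
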