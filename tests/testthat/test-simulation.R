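test_that("solo simulation produces the full session-by-trial structure", {
  envs <- quick_envs(6)
  p <- agent_params(1.5, 0.5, 0, 0.02)
  pd <- simulate_solo(p, envs, seed = 21)
  expect_s3_class(pd, "participant_data")
  expect_equal(nrow(pd$records), 150)
  expect_equal(as.integer(table(pd$records$session)), rep(25L, 6))
  expect_true(all(is.na(pd$records$partner_prev_choice)))
  pd2 <- simulate_solo(p, envs, seed = 21)
  expect_identical(pd$records, pd2$records)
})

test_that("near-infinite temperature yields uniform choice frequencies", {
  g <- grid_spec()
  env <- sample_environment(g, 1.5, seed = 5)
  p <- agent_params(1.5, 0.5, 0, 1e6)
  pd <- simulate_solo(p, rep(list(env), 200), seed = 33)  # 5000 trials
  counts <- tabulate(pd$records$choice + 1L, nbins = 165)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("pair simulation wires the one-trial-lagged partner cue", {
  envs <- quick_envs(3)
  pa <- agent_params(1.2, 0.4, 0.3, 0.03)
  pb <- agent_params(2.0, 0.6, 0.1, 0.05)
  pair <- simulate_pair(pa, pb, envs, seed = 77)
  for (s in 1:3) {
    ra <- pair$a$records[pair$a$records$session == s, ]
    rb <- pair$b$records[pair$b$records$session == s, ]
    expect_true(is.na(ra$partner_prev_choice[1]))
    expect_true(is.na(rb$partner_prev_choice[1]))
    expect_identical(ra$partner_prev_choice[-1], rb$choice[-25])
    expect_identical(rb$partner_prev_choice[-1], ra$choice[-25])
  }
  pair2 <- simulate_pair(pa, pb, envs, seed = 77)
  expect_identical(pair$a$records, pair2$a$records)
})

test_that("a gamma-zero pair is draw-for-draw two independent solo runs", {
  envs <- quick_envs(2)
  pa <- agent_params(1.2, 0.4, 0, 0.03)
  pb <- agent_params(2.0, 0.6, 0, 0.05)
  pair <- simulate_pair(pa, pb, envs, seed = 13)
  sub <- spawn_seeds(13, 2)
  solo_a <- simulate_solo(pa, envs, seed = sub[1])
  solo_b <- simulate_solo(pb, envs, seed = sub[2])
  cols <- c("session", "trial", "choice", "reward", "prob")
  expect_identical(pair$a$records[cols], solo_a$records[cols])
  expect_identical(pair$b$records[cols], solo_b$records[cols])
})

test_that("strong imitation bias pulls choices towards the partner cue", {
  envs <- quick_envs(10, seed = 442)
  near_rate <- function(gamma) {
    p <- agent_params(1.5, 0.5, gamma, 0.02)
    pair <- simulate_pair(p, p, envs, seed = 55)
    r <- pair$a$records
    ok <- !is.na(r$partner_prev_choice)
    xy <- option_coordinates(pair$a$grid, r$choice[ok])
    pxy <- option_coordinates(pair$a$grid, r$partner_prev_choice[ok])
    d <- sqrt(rowSums((xy - pxy)^2))
    mean(d <= 1)
  }
  expect_gt(near_rate(10), near_rate(0))
})

test_that("session one replays identically when later sessions are dropped", {
  envs <- quick_envs(4)
  p <- agent_params(1.5, 0.5, 0, 0.02)
  full <- simulate_solo(p, envs, seed = 61)
  first <- simulate_solo(p, envs[1], seed = 61)
  expect_identical(full$records[full$records$session == 1, ],
                   first$records)
})

test_that("synthetic cohorts reproduce the design's structure", {
  sampler_ranges <- list(lambda_hat = c(0.5, 4), beta = c(0, 1),
                         gamma = c(0, 1), tau = c(0.005, 0.2))
  cohort <- generate_synthetic_cohort(n_solo = 3, n_pairs = 2,
                                      master_seed = 9, n_envs = 4,
                                      n_trials = 5, n_truncated = 1)
  expect_length(cohort, 7)
  conds <- vapply(cohort, function(x) x$condition, character(1))
  expect_equal(sum(conds == "solo"), 3)
  expect_equal(sum(conds == "pair"), 4)
  # truncated solo participant keeps only the leading sessions
  expect_lt(nrow(cohort[[1]]$records), nrow(cohort[[2]]$records))
  for (pd in cohort) {
    tp <- pd$true_params
    for (nm in names(sampler_ranges)) {
      expect_gte(tp[[nm]], sampler_ranges[[nm]][1])
      expect_lte(tp[[nm]], sampler_ranges[[nm]][2])
    }
    if (pd$condition == "solo") {
      expect_equal(tp$gamma, 0)
      expect_true(all(is.na(pd$records$partner_prev_choice)))
    }
  }
  # full-size cohort count (structure only, no simulation)
  expect_equal(47 + 2 * 37, 121)
})

test_that("gamma sweep returns one seeded row per grid value", {
  p <- agent_params(1.59, 0.5, 0, 0.02)
  tab <- gamma_sweep(c(0, 0.18), p, n_replicates = 4, n_trials = 5,
                     master_seed = 31)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gamma, c(0, 0.18))
  expect_true(all(is.finite(tab$mean_performance)))
  tab2 <- gamma_sweep(c(0, 0.18), p, n_replicates = 4, n_trials = 5,
                      master_seed = 31)
  expect_identical(tab, tab2)
  expect_error(gamma_sweep(numeric(0), p), "non-empty")
})
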