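#' Session phases for exploration metrics
#'
#' The 25-trial session splits into three phases: trials 1-8, 9-16 and
#' 17-25. The ranges must partition the session.
#'
#' @param ranges List of three integer vectors of trial numbers.
#' @param n_trials Session length the ranges must partition.
#' @return Object of class `phase_definition`.
#' @export
phase_definition <- function(ranges = list(1:8, 9:16, 17:25), n_trials = 25L) {
  all_trials <- sort(unlist(ranges))
  if (!identical(all_trials, seq_len(n_trials))) {
    stop("phase ranges must partition trials 1..", n_trials)
  }
  structure(list(ranges = ranges, n_trials = as.integer(n_trials)),
            class = "phase_definition")
}

#' Performance summary of a trial log
#'
#' Mean raw reward per session, per trial position (across sessions), and
#' overall ("average points earned").
#'
#' @param data A [participant_data()].
#' @return List with `per_session` and `per_trial` data.frames and the
#'   scalar `overall` mean.
#' @export
performance_summary <- function(data) {
  r <- data$records
  if (nrow(r) == 0L) stop("no records")
  per_session <- stats::aggregate(reward ~ session, data = r, FUN = mean)
  names(per_session)[2] <- "mean_reward"
  per_session$n_trials <- stats::aggregate(reward ~ session, data = r,
                                           FUN = length)$reward
  per_trial <- stats::aggregate(reward ~ trial, data = r, FUN = mean)
  names(per_trial)[2] <- "mean_reward"
  list(per_session = per_session, per_trial = per_trial,
       overall = mean(r$reward))
}

#' Proportion of unique choices per phase
#'
#' A choice is unique ("new") if its option was never chosen earlier in the
#' same session; the proportion divides the unique count by the phase
#' length.
#'
#' @param data A [participant_data()].
#' @param phases A [phase_definition()].
#' @return data.frame with one row per session x phase: `n_unique`,
#'   `n_trials`, `proportion`.
#' @export
unique_choice_proportions <- function(data, phases = phase_definition()) {
  out <- lapply(split(data$records, data$records$session), function(r) {
    r <- r[order(r$trial), , drop = FALSE]
    is_new <- !duplicated(r$choice)
    do.call(rbind, lapply(seq_along(phases$ranges), function(p) {
      in_phase <- r$trial %in% phases$ranges[[p]]
      data.frame(session = r$session[1], phase = p,
                 n_unique = sum(is_new & in_phase),
                 n_trials = length(phases$ranges[[p]]),
                 proportion = sum(is_new & in_phase) / length(phases$ranges[[p]]))
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean migration length between consecutive choices
#'
#' Mean Euclidean distance on grid coordinates between the choices at
#' trials `t` and `t + 1`, per session.
#'
#' @param data A [participant_data()].
#' @return data.frame with `session` and `mean_migration`.
#' @export
migration_length <- function(data) {
  out <- lapply(split(data$records, data$records$session), function(r) {
    r <- r[order(r$trial), , drop = FALSE]
    if (nrow(r) < 2L) stop("need at least 2 trials per session")
    xy <- option_coordinates(data$grid, r$choice)
    d <- sqrt(diff(xy[, "row"])^2 + diff(xy[, "col"])^2)
    data.frame(session = r$session[1], mean_migration = mean(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Did the participant find the optimal option?
#'
#' Flags, per session, whether any choice hit the argmax of the
#' environment's mean rewards (ties: any maximal cell counts), and the
#' proportion of sessions where it did.
#'
#' @param data A [participant_data()].
#' @param envs Environment list indexed by session (defaults to the ones
#'   stored on the participant).
#' @return List with `per_session` data.frame (`session`, `found`) and the
#'   scalar `proportion`.
#' @export
optimum_found <- function(data, envs = data$envs) {
  if (is.null(envs)) stop("environments are required (none stored on data)")
  sessions <- sort(unique(data$records$session))
  found <- vapply(sessions, function(s) {
    env <- envs[[s]]
    best <- which(env$mean_rewards == max(env$mean_rewards)) - 1L
    any(data$records$choice[data$records$session == s] %in% best)
  }, logical(1))
  list(per_session = data.frame(session = sessions, found = found),
       proportion = mean(found))
}

#' Reward-prediction accuracy
#'
#' Mean absolute deviation between a participant's post-session reward
#' estimates and the true mean rewards of the probed options (the task
#' probed 16 unchosen options per session).
#'
#' @param estimates Numeric vector of predicted rewards.
#' @param truth Numeric vector of true mean rewards (same length).
#' @return Scalar mean absolute deviation.
#' @export
prediction_accuracy <- function(estimates, truth) {
  if (length(estimates) != length(truth)) {
    stop("estimates and truth must have equal length")
  }
  mean(abs(estimates - truth))
}

#' Within-pair parameter convergence
#'
#' Compares fitted parameters within real pairs against shuffled pairs
#' (random re-pairings of pair-condition participants that never reproduce
#' a true pairing) and nominal pairs (random pairings of solo
#' participants). Reports per-parameter within-pair absolute differences
#' for each pairing type and Spearman rank correlations of parameters
#' across real pairs.
#'
#' @param fits data.frame as from [fits_to_data_frame()] (one row per
#'   participant; needs `participant_id`, `condition`, `pair_id` and the
#'   parameter columns).
#' @param params Parameter columns to analyse.
#' @param n_shuffles Number of shuffled (and nominal) pairings drawn.
#' @param seed Integer seed for the shuffles.
#' @return Object of class `pair_convergence_result`: list with
#'   `differences` (data.frame: pairing type, parameter, absolute
#'   difference) and `correlations` (per-parameter Spearman rho with
#'   p-value across real pairs).
#' @export
pair_convergence <- function(fits, params = c("lambda_hat", "beta", "gamma", "tau"),
                             n_shuffles = 100L, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  pairf <- fits[fits$condition == "pair" & !is.na(fits$pair_id), , drop = FALSE]
  solof <- fits[fits$condition == "solo", , drop = FALSE]
  by_pair <- split(pairf, pairf$pair_id)
  by_pair <- by_pair[vapply(by_pair, nrow, integer(1)) == 2L]
  if (length(by_pair) < 2L) stop("need at least 2 complete pairs")

  abs_diff <- function(a, b) {
    do.call(rbind, lapply(params, function(p) {
      data.frame(parameter = p, abs_difference = abs(a[[p]] - b[[p]]))
    }))
  }
  real <- do.call(rbind, lapply(names(by_pair), function(id) {
    g <- by_pair[[id]]
    cbind(pairing = "real", abs_diff(g[1, ], g[2, ]))
  }))

  true_pairs <- vapply(by_pair, function(g)
    paste(sort(g$participant_id), collapse = "|"), character(1))
  draw_pairings <- function(pool, forbidden) {
    reps <- list()
    n_draws <- 0L
    while (length(reps) < n_shuffles && n_draws < n_shuffles * 50L) {
      n_draws <- n_draws + 1L
      idx <- sample(nrow(pool), 2L)
      key <- paste(sort(pool$participant_id[idx]), collapse = "|")
      if (key %in% forbidden) next
      reps[[length(reps) + 1L]] <- abs_diff(pool[idx[1], ], pool[idx[2], ])
    }
    do.call(rbind, reps)
  }
  shuffled <- if (nrow(pairf) >= 4L) {
    cbind(pairing = "shuffled", draw_pairings(pairf, true_pairs))
  } else NULL
  nominal <- if (nrow(solof) >= 2L) {
    cbind(pairing = "nominal", draw_pairings(solof, character(0)))
  } else NULL
  differences <- rbind(real, shuffled, nominal)
  rownames(differences) <- NULL

  a_mat <- do.call(rbind, lapply(by_pair, function(g) g[1, params]))
  b_mat <- do.call(rbind, lapply(by_pair, function(g) g[2, params]))
  correlations <- do.call(rbind, lapply(params, function(p) {
    ct <- suppressWarnings(
      stats::cor.test(a_mat[[p]], b_mat[[p]], method = "spearman"))
    data.frame(parameter = p, rho = unname(ct$estimate), p_value = ct$p.value)
  }))
  structure(list(differences = differences, correlations = correlations,
                 n_pairs = length(by_pair)),
            class = "pair_convergence_result")
}

#' @export
print.pair_convergence_result <- function(x, ...) {
  cat(sprintf("<pair_convergence_result> %d real pairs\n", x$n_pairs))
  med <- stats::aggregate(abs_difference ~ pairing + parameter,
                          data = x$differences, FUN = stats::median)
  print(med, row.names = FALSE)
  cat("across-pair Spearman correlations:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
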