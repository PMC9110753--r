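# Flatten a participant's records into the vectors the C++ replay consumes.
flatten_records <- function(data) {
  r <- data$records
  ord <- order(r$session, r$trial)
  r <- r[ord, , drop = FALSE]
  partner <- r$partner_prev_choice
  partner[is.na(partner)] <- -1L
  list(session = as.integer(r$session), choice = as.integer(r$choice),
       reward_scaled = scale_rewards(r$reward), partner = as.integer(partner))
}

#' Per-trial log probabilities of a participant's choices
#'
#' Replays the trial log under the model: within each session the GP
#' posterior is conditioned only on that participant's own past
#' choices/rewards, values and softmax probabilities are computed per
#' trial, and the chosen option's log probability is returned. Trial 1
#' uses the prior-only posterior.
#'
#' @param data A [participant_data()].
#' @param params An [agent_params()].
#' @param spec A [model_spec()].
#' @param noise_var GP observation-noise variance on the scaled scale.
#' @return Numeric vector, one log probability per trial.
#' @export
trial_log_probs <- function(data, params, spec, noise_var = 1e-4) {
  if (spec$use_social && data$condition == "solo") {
    stop("social term active but data are from the solo condition")
  }
  fl <- flatten_records(data)
  lam <- if (is.null(spec$lambda_fixed)) params$lambda_hat else spec$lambda_fixed
  cpp_trial_logprobs(fl$session, fl$choice, fl$reward_scaled, fl$partner,
                     squared_distances(data$grid), lam, params$beta,
                     params$gamma, params$tau, spec$use_uncertainty,
                     spec$use_social, noise_var)
}

#' Negative log likelihood of a participant's choices
#'
#' Sum of `-log P(choice_t)` over all trials (sessions independent, beliefs
#' reset at session boundaries). Always non-negative.
#'
#' @inheritParams trial_log_probs
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(data, params, spec = model_spec(),
                                    noise_var = 1e-4) {
  -sum(trial_log_probs(data, params, spec, noise_var))
}

#' Akaike Information Criterion
#'
#' `AIC = -2 * log_lik + 2 * k` for a model with `k` free parameters.
#'
#' @param log_lik Maximized log likelihood.
#' @param k Number of free parameters.
#' @return AIC value.
#' @export
aic <- function(log_lik, k) {
  if (k < 0) stop("k must be non-negative")
  -2 * log_lik + 2 * k
}

#' Default fitting bounds
#'
#' Box bounds for the four parameters on the scaled-reward scale:
#' `lambda_hat` in `[0.1, 10]`, `beta` in `[0, 5]`, `gamma` in `[0, 5]`,
#' `tau` in `[0.001, 1]`. These bracket the empirically reported medians
#' with wide margins.
#'
#' @return Named list of length-2 numeric bounds.
#' @export
default_bounds <- function() {
  list(lambda_hat = c(0.1, 10), beta = c(0, 5), gamma = c(0, 5),
       tau = c(0.001, 1))
}

#' Fit a choice model to one participant by maximum likelihood
#'
#' Minimizes the negative log likelihood over the model's free parameters
#' with the seeded differential-evolution optimizer within box bounds.
#'
#' @param data A [participant_data()].
#' @param spec A [model_spec()] selecting the model.
#' @param bounds Named bounds list as from [default_bounds()].
#' @param settings [de_settings()] for the optimizer.
#' @param seed Integer optimizer seed (mandatory for reproducible fits).
#' @param noise_var GP observation-noise variance on the scaled scale.
#' @return Object of class `fit_result`: list with `params`
#'   ([agent_params()]; inactive components set to 0, fixed length-scale
#'   substituted), `log_lik`, `aic`, `k`, `converged`, `n_trials_used`,
#'   `optimizer_seed`, `n_evals`, `model`, and the participant identifiers.
#' @export
fit_participant <- function(data, spec = model_spec(), bounds = default_bounds(),
                            settings = de_settings(), seed = NULL,
                            noise_var = 1e-4) {
  if (nrow(data$records) == 0L) stop("participant has no records")
  if (spec$use_social && data$condition == "solo") {
    stop("social term active but data are from the solo condition")
  }
  fl <- flatten_records(data)
  d2 <- squared_distances(data$grid)
  free <- spec$free_params
  lo <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  hi <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  objective <- function(theta) {
    names(theta) <- free
    lam <- if (is.null(spec$lambda_fixed)) theta[["lambda_hat"]] else spec$lambda_fixed
    b <- if (spec$use_uncertainty) theta[["beta"]] else 0
    g <- if (spec$use_social) theta[["gamma"]] else 0
    -sum(cpp_trial_logprobs(fl$session, fl$choice, fl$reward_scaled,
                            fl$partner, d2, lam, b, g, theta[["tau"]],
                            spec$use_uncertainty, spec$use_social, noise_var))
  }
  opt <- de_optim(objective, lo, hi, settings = settings, seed = seed)
  theta <- opt$par
  names(theta) <- free
  params <- agent_params(
    lambda_hat = if (is.null(spec$lambda_fixed)) theta[["lambda_hat"]] else spec$lambda_fixed,
    beta = if (spec$use_uncertainty) theta[["beta"]] else 0,
    gamma = if (spec$use_social) theta[["gamma"]] else 0,
    tau = theta[["tau"]]
  )
  log_lik <- -opt$value
  structure(
    list(params = params, log_lik = log_lik, aic = aic(log_lik, spec$k),
         k = spec$k, converged = opt$converged,
         n_trials_used = nrow(data$records),
         optimizer_seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         n_evals = opt$n_evals, model = spec$name,
         participant_id = data$participant_id, condition = data$condition,
         pair_id = data$pair_id),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s / %s: LL = %.2f, AIC = %.2f (k = %d)%s\n  lambda_hat = %.3f, beta = %.3f, gamma = %.3f, tau = %.4f\n",
    x$participant_id, x$model, x$log_lik, x$aic, x$k,
    if (!x$converged) " [generation cap reached]" else "",
    x$params$lambda_hat, x$params$beta, x$params$gamma, x$params$tau))
  invisible(x)
}

#' Turn a list of fit results into a data.frame
#'
#' @param fits List of `fit_result` objects.
#' @return data.frame, one row per fit.
#' @export
fits_to_data_frame <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(participant_id = f$participant_id, condition = f$condition,
               pair_id = ifelse(is.na(f$pair_id), NA_character_,
                                as.character(f$pair_id)),
               model = f$model, lambda_hat = f$params$lambda_hat,
               beta = f$params$beta, gamma = f$params$gamma,
               tau = f$params$tau, log_lik = f$log_lik, k = f$k,
               aic = f$aic, converged = f$converged,
               n_trials_used = f$n_trials_used,
               optimizer_seed = f$optimizer_seed)
  }))
}

#' Fit a model family to a cohort and compare by AIC
#'
#' Fits every model in `family` to every participant and reports the
#' per-model mean AIC plus each participant's best (minimum-AIC) model.
#' Social models are skipped for solo participants (their logs carry no
#' partner cue); skipped combinations are excluded from the means.
#'
#' @param cohort List of [participant_data()].
#' @param family Named list of [model_spec()], e.g.
#'   [default_model_family()].
#' @param bounds,settings,noise_var Passed to [fit_participant()].
#' @param master_seed Spawns one optimizer seed per (participant, model).
#' @return Object of class `model_comparison`: list with `fits`
#'   (data.frame), `mean_aic` (data.frame sorted by mean AIC), and `best`
#'   (per-participant winner with delta-AIC to runner-up).
#' @export
compare_models <- function(cohort, family = default_model_family(),
                           bounds = default_bounds(),
                           settings = de_settings(), master_seed = NULL,
                           noise_var = 1e-4) {
  if (length(cohort) < 1L) stop("cohort must contain at least one participant")
  if (length(family) < 2L) stop("need at least two models to compare")
  seeds <- matrix(spawn_seeds(master_seed, length(cohort) * length(family)),
                  nrow = length(cohort))
  fits <- list()
  for (i in seq_along(cohort)) {
    for (j in seq_along(family)) {
      spec <- family[[j]]
      if (spec$use_social && cohort[[i]]$condition == "solo") next
      f <- fit_participant(cohort[[i]], spec, bounds, settings,
                           seed = seeds[i, j], noise_var = noise_var)
      fits[[length(fits) + 1L]] <- f
    }
  }
  df <- fits_to_data_frame(fits)
  mean_aic <- stats::aggregate(aic ~ model, data = df, FUN = mean)
  mean_aic$n <- stats::aggregate(aic ~ model, data = df, FUN = length)$aic
  mean_aic <- mean_aic[order(mean_aic$aic), , drop = FALSE]
  names(mean_aic)[2] <- "mean_aic"
  best <- do.call(rbind, lapply(split(df, df$participant_id), function(g) {
    g <- g[order(g$aic), , drop = FALSE]
    data.frame(participant_id = g$participant_id[1], best_model = g$model[1],
               best_aic = g$aic[1],
               delta_aic_next = if (nrow(g) > 1) g$aic[2] - g$aic[1] else NA_real_)
  }))
  rownames(best) <- NULL
  structure(list(fits = df, mean_aic = mean_aic, best = best),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> mean AIC by model:\n")
  print(x$mean_aic, row.names = FALSE)
  tab <- table(x$best$best_model)
  cat("participants best fit by:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
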