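#' Agent parameters of the UCB+S choice model
#'
#' The four free parameters: `lambda_hat` (subjective belief about the
#' spatial length-scale), `beta` (uncertainty premium on the predictive sd),
#' `gamma` (imitation bias towards the partner's previous choice), and
#' `tau` (softmax temperature, i.e. random exploration).
#'
#' @param lambda_hat Positive length-scale belief.
#' @param beta Non-negative uncertainty premium.
#' @param gamma Non-negative imitation bias.
#' @param tau Positive softmax temperature.
#' @return Object of class `agent_params`.
#' @export
#' @examples
#' agent_params(lambda_hat = 1.5, beta = 0.5, gamma = 0.18, tau = 0.02)
agent_params <- function(lambda_hat, beta = 0, gamma = 0, tau) {
  if (!is.finite(lambda_hat) || lambda_hat <= 0) stop("lambda_hat must be positive")
  if (!is.finite(beta) || beta < 0) stop("beta must be non-negative")
  if (!is.finite(gamma) || gamma < 0) stop("gamma must be non-negative")
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  structure(list(lambda_hat = lambda_hat, beta = beta, gamma = gamma, tau = tau),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> lambda_hat = %g, beta = %g, gamma = %g, tau = %g\n",
              x$lambda_hat, x$beta, x$gamma, x$tau))
  invisible(x)
}

#' Model specification within the UCB+S family
#'
#' Toggles which components of the valuation enter the model. The full
#' UCB+S model has both the uncertainty term and the social term active;
#' sub-models switch them off. `lambda_fixed` freezes the length-scale at a
#' given value instead of fitting it (used for the degenerate variants with
#' essentially no spatial generalization).
#'
#' @param use_uncertainty Is the `beta * s(x)` term active?
#' @param use_social Is the `gamma * k(x, x_partner)` term active?
#' @param name Model label.
#' @param lambda_fixed `NULL` (fit `lambda_hat`) or a positive value.
#' @return Object of class `model_spec` with a parameter count `k`
#'   (number of free parameters: `lambda_hat` unless fixed, `tau`, plus one
#'   per active term).
#' @export
model_spec <- function(use_uncertainty = TRUE, use_social = TRUE,
                       name = NULL, lambda_fixed = NULL) {
  if (!is.null(lambda_fixed) && lambda_fixed <= 0) {
    stop("lambda_fixed must be positive when given")
  }
  if (is.null(name)) {
    name <- paste0("m", if (use_uncertainty) "+bs", if (use_social) "+soc",
                   if (!is.null(lambda_fixed)) "(lambda fixed)")
  }
  free <- c(if (is.null(lambda_fixed)) "lambda_hat", "tau",
            if (use_uncertainty) "beta", if (use_social) "gamma")
  structure(
    list(use_uncertainty = isTRUE(use_uncertainty),
         use_social = isTRUE(use_social),
         name = name, lambda_fixed = lambda_fixed,
         free_params = free, k = length(free)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: free = {%s}, k = %d\n",
              x$name, paste(x$free_params, collapse = ", "), x$k))
  invisible(x)
}

#' Default model family for AIC comparison
#'
#' The full UCB+S model and its sub-models: dropping the social term, the
#' uncertainty term, or both, plus two degenerate variants with the
#' length-scale frozen near zero (no spatial generalization), with and
#' without the uncertainty term. The family is a reconstruction of the
#' standard sub-model lattice for this model class.
#'
#' @param include_degenerate Include the two `lambda_fixed` variants.
#' @param social Restrict to models whose social flag is in this set; pass
#'   `FALSE` to get the solo-condition family.
#' @return Named list of [model_spec()] objects.
#' @export
default_model_family <- function(include_degenerate = TRUE, social = c(TRUE, FALSE)) {
  fam <- list(
    ucbs    = model_spec(TRUE,  TRUE,  name = "UCB+S"),
    ucb     = model_spec(TRUE,  FALSE, name = "UCB"),
    m_soc   = model_spec(FALSE, TRUE,  name = "Mean+S"),
    m_only  = model_spec(FALSE, FALSE, name = "Mean"),
    local_b = model_spec(TRUE,  FALSE, name = "Local+BS", lambda_fixed = 1e-6),
    local   = model_spec(FALSE, FALSE, name = "Local", lambda_fixed = 1e-6)
  )
  if (!include_degenerate) fam <- fam[1:4]
  fam[vapply(fam, function(m) m$use_social %in% social, logical(1))]
}

#' Upper-confidence-bound values
#'
#' `UCB(x) = m(x) + beta * s(x)` over all options.
#'
#' @param post A [gp_posterior()].
#' @param beta Non-negative uncertainty premium.
#' @return Numeric vector of option values.
#' @export
ucb_values <- function(post, beta) {
  if (!is.finite(beta) || beta < 0) stop("beta must be non-negative")
  post$mean + beta * post$sd
}

#' Kernel-shaped social bonus around the partner's previous choice
#'
#' The vicarious value of the option the partner chose on the previous
#' trial is 1 and decays with squared distance under the agent's own RBF
#' kernel: `k(x, x_partner)` with length-scale `lambda_hat`. With no
#' partner cue (trial 1, or solo condition) the bonus is zero everywhere.
#'
#' @param partner_index 0-based option index of the partner's previous
#'   choice, or `NA`/`NULL` when absent.
#' @param lambda_hat Positive length-scale.
#' @param grid A [grid_spec()].
#' @return Numeric vector in `[0, 1]` of length `grid$n_options`.
#' @export
social_bonus <- function(partner_index, lambda_hat, grid = grid_spec()) {
  if (is.null(partner_index) || length(partner_index) == 0L || is.na(partner_index)) {
    return(rep(0, grid$n_options))
  }
  rbf_kernel(0:(grid$n_options - 1L), rep(partner_index, grid$n_options),
             lambda_hat, grid)
}

#' Total option values under the UCB+S model
#'
#' `V(x) = m(x) + beta * s(x) + gamma * k(x, x_partner)`, with the last two
#' terms gated by the model flags. The additive breakdown is recorded in
#' the result.
#'
#' @param post A [gp_posterior()].
#' @param params An [agent_params()].
#' @param spec A [model_spec()].
#' @param partner_index 0-based partner cue index or `NA`/`NULL`.
#' @param grid A [grid_spec()].
#' @param solo Is this solo-condition data? Activating the social flag on
#'   solo data is a contract error.
#' @return Object of class `value_vector`: list with `values` and a
#'   `components` list (`mean`, `uncertainty`, `social`).
#' @export
total_values <- function(post, params, spec, partner_index = NULL,
                         grid = grid_spec(), solo = FALSE) {
  if (spec$use_social && solo) {
    stop("social term active but data are from the solo condition")
  }
  unc <- if (spec$use_uncertainty) params$beta * post$sd else rep(0, length(post$sd))
  soc <- if (spec$use_social) {
    params$gamma * social_bonus(partner_index, params$lambda_hat, grid)
  } else rep(0, length(post$mean))
  structure(
    list(values = post$mean + unc + soc,
         components = list(mean = post$mean, uncertainty = unc, social = soc)),
    class = "value_vector"
  )
}

#' Softmax choice probabilities
#'
#' `P(x_j) = exp(V_j / tau) / sum_k exp(V_k / tau)`, computed with
#' max-subtraction for numerical stability at small temperatures.
#'
#' @param values A `value_vector` from [total_values()] or a plain numeric
#'   vector of option values.
#' @param tau Positive softmax temperature.
#' @return Object of class `choice_probabilities`: list with `probs`
#'   (strictly positive, sums to 1).
#' @export
softmax_probs <- function(values, tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  v <- if (inherits(values, "value_vector")) values$values else values
  z <- v / tau
  z <- z - max(z)
  e <- exp(z)
  structure(list(probs = e / sum(e)), class = "choice_probabilities")
}
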