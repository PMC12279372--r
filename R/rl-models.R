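#' Model specifications for the nested Pearce-Hall hybrid family
#'
#' Four nested models of trial-and-error learning with counterfactual
#' feedback:
#' * **M1** — constant-learning-rate Q-learning with a play bias; the
#'   learning rate is the logistic of a single intercept weight.
#' * **M2** — Pearce-Hall hybrid: the learning rate is `kappa * A`, where
#'   the associability `A` tracks the absolute prediction error with step
#'   size `eta`.
#' * **M3** — M2 plus a confirmatory-feedback predictor in the logistic
#'   `kappa` (confirmatory = factual win or counterfactual loss).
#' * **M4** — M3 plus a feedback-modality predictor (factual vs
#'   counterfactual).
#'
#' @param name One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @return A `model_spec` list with fields `name`, `uses_associability`,
#'   `kappa_predictors`, `param_names`, `n_params`, and default box
#'   `bounds` used in fitting.
#' @export
#' @examples
#' model_spec("M3")$param_names
model_spec <- function(name = c("M1", "M2", "M3", "M4")) {
  name <- match.arg(name)
  kappa_predictors <- switch(name,
    M1 = "intercept", M2 = "intercept",
    M3 = c("intercept", "confirmatory"),
    M4 = c("intercept", "confirmatory", "modality"))
  uses_assoc <- name != "M1"
  param_names <- c("beta", "play_bias",
                   paste0("kappa_", kappa_predictors),
                   if (uses_assoc) "eta")
  lower <- c(0, -3, rep(-10, length(kappa_predictors)),
             if (uses_assoc) 0)
  upper <- c(10, 3, rep(10, length(kappa_predictors)),
             if (uses_assoc) 1)
  structure(list(name = name,
                 uses_associability = uses_assoc,
                 kappa_predictors = kappa_predictors,
                 param_names = param_names,
                 n_params = length(param_names),
                 bounds = list(lower = setNames(lower, param_names),
                               upper = setNames(upper, param_names))),
            class = "model_spec")
}

#' Construct an agent parameter vector
#'
#' @param beta Softmax inverse temperature (>= 0).
#' @param play_bias Additive bias on the played option's value.
#' @param kappa_intercept,kappa_confirmatory,kappa_modality Weights of the
#'   logistic learning-rate scale; only those active in `spec` are used.
#' @param eta Associability step size in `[0, 1]` (hybrid models only).
#' @param spec A [model_spec()]; defaults to the richest model consistent
#'   with the supplied arguments.
#' @return A named numeric vector ordered as `spec$param_names`.
#' @export
agent_params <- function(beta, play_bias = 0, kappa_intercept = 0,
                         kappa_confirmatory = NULL, kappa_modality = NULL,
                         eta = NULL, spec = NULL) {
  if (is.null(spec)) {
    name <- if (!is.null(kappa_modality)) "M4"
            else if (!is.null(kappa_confirmatory)) "M3"
            else if (!is.null(eta)) "M2" else "M1"
    spec <- model_spec(name)
  }
  full <- c(beta = beta, play_bias = play_bias,
            kappa_intercept = kappa_intercept,
            kappa_confirmatory = kappa_confirmatory %||% NA_real_,
            kappa_modality = kappa_modality %||% NA_real_,
            eta = eta %||% NA_real_)
  out <- full[spec$param_names]
  if (anyNA(out))
    abort(sprintf("Missing parameters for %s: %s", spec$name,
                  paste(names(out)[is.na(out)], collapse = ", ")))
  validate_params(out, spec)
  out
}

validate_params <- function(params, spec) {
  stopifnot(length(params) == spec$n_params)
  b <- spec$bounds
  bad <- params < b$lower[names(params)] - 1e-9 |
         params > b$upper[names(params)] + 1e-9
  if (any(bad))
    abort(sprintf("Parameters out of bounds: %s",
                  paste(names(params)[bad], collapse = ", ")))
  invisible(params)
}

#' Classify feedback modality and confirmation
#'
#' Feedback is factual when the agent played and counterfactual (fictive)
#' when it passed; it is confirmatory when it supports the chosen policy —
#' a factual win or a counterfactual loss — and disconfirmatory otherwise.
#'
#' @param action Character vector, `"play"` or `"pass"`.
#' @param outcome_valence Character vector, `"win"` or `"loss"`.
#' @return A tibble with columns `modality` (`"factual"`/
#'   `"counterfactual"`) and `confirmatory` (logical).
#' @export
#' @examples
#' classify_feedback(c("play", "pass"), c("win", "loss"))
classify_feedback <- function(action, outcome_valence) {
  stopifnot(all(action %in% c("play", "pass")),
            all(outcome_valence %in% c("win", "loss")))
  modality <- ifelse(action == "play", "factual", "counterfactual")
  confirmatory <- (modality == "factual" & outcome_valence == "win") |
                  (modality == "counterfactual" & outcome_valence == "loss")
  tibble::tibble(modality = modality, confirmatory = confirmatory)
}

# Centered +/-0.5 coding of the binary kappa predictors; the intercept is
# therefore the grand-mean logit of the learning-rate scale.
kappa_features <- function(spec, confirmatory, modality) {
  x <- matrix(1, nrow = length(confirmatory),
              ncol = length(spec$kappa_predictors),
              dimnames = list(NULL, spec$kappa_predictors))
  if ("confirmatory" %in% spec$kappa_predictors)
    x[, "confirmatory"] <- ifelse(confirmatory, 0.5, -0.5)
  if ("modality" %in% spec$kappa_predictors)
    x[, "modality"] <- ifelse(modality == "factual", 0.5, -0.5)
  x
}

#' Learning-rate scale from the logistic predictor model
#'
#' `kappa = logistic(w . x)` with `x` the trial's predictor vector
#' (intercept 1; confirmatory and modality coded +0.5/-0.5).
#'
#' @param weights Numeric weight vector, ordered as
#'   `spec$kappa_predictors`.
#' @param features Numeric matrix (trials x predictors) or vector.
#' @return Numeric vector of scales in (0, 1).
#' @export
kappa_scale <- function(weights, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(weights))
    abort("Length of `weights` must match the number of feature columns.")
  plogis(drop(features %*% weights))
}

#' Pearce-Hall associability update
#'
#' `A' = eta * |delta| + (1 - eta) * A`: a running average of the
#' absolute prediction error with step size `eta`. The recursion is not
#' artificially bounded — with rewards coded +1/-1 a surprising outcome
#' can push `A` above 1, and a large learning-rate scale then yields an
#' effective learning rate above 1. That destabilizing regime (value
#' overshooting, growing prediction errors) is exactly how very flexible
#' learners come apart on this task, so it is modelled, not clipped.
#'
#' @param A Current associability (>= 0).
#' @param delta Prediction error.
#' @param eta Step size in `[0, 1]`.
#' @return Updated associability.
#' @export
update_associability <- function(A, delta, eta) {
  stopifnot(all(A >= 0), all(eta >= 0 & eta <= 1))
  eta * abs(delta) + (1 - eta) * A
}

#' Rescorla-Wagner value update
#'
#' `delta = R - Q`; `Q' = Q + alpha * delta` with the internal reward
#' signal `R` in `{+1, -1}` (displayed as +/-10 points).
#'
#' @param Q Current expected value.
#' @param alpha Learning rate (`kappa * A`; can exceed 1 when the
#'   associability is inflated, in which case the update overshoots).
#' @param R Reward signal, +1 (win) or -1 (loss).
#' @return A list with `Q` (updated value) and `delta`.
#' @export
update_value <- function(Q, alpha, R) {
  stopifnot(all(alpha >= 0))
  delta <- R - Q
  list(Q = Q + alpha * delta, delta = delta)
}

#' Softmax probability of playing
#'
#' The played option's value is `play_bias + Q`; passing has value 0, so
#' `p_play = logistic(beta * (play_bias + Q))`.
#'
#' @param Q Expected value of the shown stimulus.
#' @param play_bias Additive play bias.
#' @param beta Inverse temperature (>= 0).
#' @return Probability of playing.
#' @export
choice_probability <- function(Q, play_bias = 0, beta = 1) {
  stopifnot(all(beta >= 0))
  plogis(beta * (play_bias + Q))
}

# Internal bridge to the compiled recursion. `action` NULL => simulate.
rl_engine <- function(params, spec, schedule, action = NULL) {
  validate_params(params, spec)
  nk <- length(spec$kappa_predictors)
  kw <- unname(params[paste0("kappa_", spec$kappa_predictors)])
  eta <- if (spec$uses_associability) unname(params["eta"]) else 0
  simulate <- is.null(action)
  act <- if (simulate) integer(nrow(schedule))
         else as.integer(action == "play")
  rl_engine_cpp(unname(params["beta"]), unname(params["play_bias"]), kw,
                eta, spec$uses_associability, nk,
                max(schedule$stimulus), schedule$stimulus,
                as.integer(schedule$outcome_valence == "win"),
                act, simulate)
}

#' Simulate an agent playing the task
#'
#' Runs the model forward on a schedule: on every trial the agent's play
#' probability comes from the current value of the shown stimulus, an
#' action is sampled, the (pre-drawn) outcome is observed — factually on
#' play, fictively on pass — and value and associability are updated.
#' Values and associabilities are tracked per stimulus; the update order
#' within a trial is choice, outcome, value update with the current
#' associability, then associability update for the stimulus's next
#' encounter.
#'
#' @param params Named parameter vector (see [agent_params()]).
#' @param spec A [model_spec()].
#' @param schedule A schedule from [build_schedule()] with outcome
#'   valences drawn.
#' @param seed Optional RNG seed.
#' @return The schedule tibble extended with behavioural columns
#'   (`action`, `modality`, `confirmatory`, `R`, `points`) and latent
#'   columns (`q`, `delta`, `assoc`, `alpha`, `p_play`); total realized
#'   points are in `attr(, "total_points")`.
#' @export
simulate_agent <- function(params, spec, schedule, seed = NULL) {
  force(params); force(spec); force(schedule)
  with_seed(seed, {
    res <- rl_engine(params, spec, schedule)
    out <- assemble_trials(schedule, res)
    attr(out, "params") <- params
    attr(out, "spec") <- spec$name
    attr(out, "total_points") <- sum(out$points)
    out
  })
}

assemble_trials <- function(schedule, res) {
  ppo <- attr(schedule, "task_config")$points_per_outcome %||% 10
  dplyr::mutate(schedule,
    action = ifelse(res$action == 1, "play", "pass"),
    modality = ifelse(res$modality == 1, "factual", "counterfactual"),
    confirmatory = res$confirmatory == 1,
    R = ifelse(.data$outcome_valence == "win", 1, -1),
    points = ifelse(.data$action == "play", ppo * .data$R, 0),
    q = res$q, delta = res$delta, assoc = res$assoc,
    alpha = res$alpha, p_play = res$p_play)
}

#' Latent trajectories implied by observed choices
#'
#' Replays the model's deterministic recursion through a trial dataset
#' (actions and outcomes fixed), returning the per-trial latents. The
#' recursion is the same code path as [simulate_agent()], so simulating
#' and then scoring the simulated actions reproduces the stored latents
#' exactly.
#'
#' @inheritParams simulate_agent
#' @param data A trial dataset with `stimulus`, `action` and
#'   `outcome_valence`.
#' @return `data` with latent columns `q`, `delta`, `assoc`, `alpha`,
#'   `p_play` (and feedback classification) refreshed.
#' @export
rl_latents <- function(params, spec, data) {
  res <- rl_engine(params, spec, data, action = data$action)
  out <- data
  out$modality <- ifelse(res$modality == 1, "factual", "counterfactual")
  out$confirmatory <- res$confirmatory == 1
  out$R <- ifelse(out$outcome_valence == "win", 1, -1)
  out$q <- res$q; out$delta <- res$delta; out$assoc <- res$assoc
  out$alpha <- res$alpha; out$p_play <- res$p_play
  out
}

#' Default weakly-informative priors for MAP estimation
#'
#' Normal(0, 10^2) on the unbounded parameters (play bias and kappa
#' weights), uniform on the boxes for `beta` (`[0, 10]`) and `eta`
#' (`[0, 1]`). With these, the MAP estimate is essentially a bounded
#' maximum-likelihood estimate.
#'
#' @return A function `(params, spec) -> log prior density`.
#' @export
default_prior <- function() {
  function(params, spec) {
    lp <- dunif(params["beta"], 0, 10, log = TRUE) +
      dnorm(params["play_bias"], 0, 10, log = TRUE) +
      sum(dnorm(params[paste0("kappa_", spec$kappa_predictors)], 0, 10,
                log = TRUE))
    if (spec$uses_associability)
      lp <- lp + dunif(params["eta"], 0, 1, log = TRUE)
    unname(lp)
  }
}

#' Negative log posterior of a trial dataset
#'
#' The choice log likelihood under the model's latent recursion plus the
#' log prior, negated. A probability floor of `1e-12` inside the log keeps
#' the objective finite everywhere in the box.
#'
#' @inheritParams rl_latents
#' @param log_prior A log-prior function as returned by [default_prior()],
#'   or `NULL` for pure negative log likelihood.
#' @return Scalar negative log posterior.
#' @export
negative_log_posterior <- function(params, spec, data,
                                   log_prior = default_prior()) {
  validate_params(params, spec)
  nll <- rl_choice_nll(params, spec, data)
  if (!is.null(log_prior)) nll <- nll - log_prior(params, spec)
  nll
}

# Choice negative log likelihood (no prior); objective hot path.
rl_choice_nll <- function(params, spec, data) {
  nk <- length(spec$kappa_predictors)
  kw <- unname(params[paste0("kappa_", spec$kappa_predictors)])
  eta <- if (spec$uses_associability) unname(params["eta"]) else 0
  rl_nll_cpp(unname(params["beta"]), unname(params["play_bias"]), kw, eta,
             spec$uses_associability, nk, max(data$stimulus),
             data$stimulus, as.integer(data$outcome_valence == "win"),
             as.integer(data$action == "play"))
}
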