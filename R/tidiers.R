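#' Tidy a fitted subject
#'
#' @param x An `rl_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.rl_fit
#' @return `glance()`: one-row model summary with `model`, `log_lik`,
#'   `log_posterior`, `bic`, `n_trials`, `n_params`, `converged`.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(model = x$spec$name, log_lik = x$log_lik,
                 log_posterior = x$log_posterior, bic = x$bic,
                 n_trials = x$n_trials, n_params = x$spec$n_params,
                 converged = x$converged)
}

#' Tidy a Bayesian model-selection result
#'
#' @param x An `rl_bms`.
#' @param ... Unused.
#' @return One row per model: Dirichlet `alpha`, `expected_freq`, the
#'   exceedance probability `xp` and protected exceedance `pxp`.
#' @export
tidy.rl_bms <- function(x, ...) {
  tibble::tibble(model = names(x$alpha), alpha = unname(x$alpha),
                 expected_freq = unname(x$expected_freq),
                 xp = unname(x$xp), pxp = unname(x$pxp))
}

#' @rdname tidy.rl_bms
#' @return `glance()`: one row with `n_subjects`, `n_models`, `bor`.
#' @export
glance.rl_bms <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$alpha),
                 bor = x$bor)
}

#' Tidy a structural-break result
#'
#' @param x A `break_result`.
#' @param ... Unused.
#' @return The per-segment tibble with a `segment` index.
#' @export
tidy.break_result <- function(x, ...) {
  dplyr::mutate(x$segments, segment = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.break_result
#' @export
glance.break_result <- function(x, ...) {
  tibble::tibble(n_breaks = x$n_breaks,
                 first_break = if (length(x$break_positions))
                   x$break_positions[1] else NA_integer_,
                 flagged = x$flagged)
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The per-parameter recovery tibble (`parameter`, `r`, `bias`,
#'   `rmse`, `n`).
#' @export
tidy.recovery_report <- function(x, ...) x$parameters

#' Plot reversal-aligned learning curves
#'
#' @param object A `learning_curve` tibble from [reversal_curves()].
#' @param ... Unused.
#' @return A ggplot: probability correct vs trials since reversal,
#'   colored by outcome-noise level (faceted by extra grouping columns
#'   when present).
#' @export
autoplot.learning_curve <- function(object, ...) {
  extra <- setdiff(names(object),
                   c("noise_level", "position", "raw", "value", "n"))
  p <- ggplot2::ggplot(object,
         ggplot2::aes(x = .data$position, y = .data$value,
                      colour = .data$noise_level)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3,
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Trials since reversal", y = "P(correct)",
                  colour = "Outcome noise") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (length(extra))
    p <- p + ggplot2::facet_wrap(extra)
  p
}

#' Plot an eta sweep
#'
#' @param object An `eta_sweep` tibble from [eta_sweep()].
#' @param ... Unused.
#' @return A ggplot of mean total points (with +/-1 SE ribbon) against
#'   the associability step size.
#' @export
autoplot.eta_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$eta,
                                       y = .data$mean_points)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_points - .data$se_points,
      ymax = .data$mean_points + .data$se_points), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(eta), y = "Mean total points") +
    ggplot2::theme_minimal()
}

#' Plot filter trajectories
#'
#' @param object A `vkf_run` or `vkf_sim` tibble.
#' @param ... Unused.
#' @return A ggplot with the belief mean, learning rate, volatility and
#'   stochasticity trajectories in facets.
#' @export
autoplot.vkf_run <- function(object, ...) {
  long <- object |>
    dplyr::select(dplyr::any_of(c("trial", "m", "alpha", "volatility",
                                  "stochasticity"))) |>
    tidyr::pivot_longer(-"trial", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vkf_run
#' @export
autoplot.vkf_sim <- function(object, ...) autoplot.vkf_run(object, ...)

#' Plot per-trial latent trajectories of a simulated agent
#'
#' @param data A trial tibble with latent columns (from
#'   [simulate_agent()] or [rl_latents()]).
#' @return A ggplot of value, learning rate and associability over
#'   trials, one facet per stimulus.
#' @export
plot_latents <- function(data) {
  long <- data |>
    dplyr::select(dplyr::all_of(c("trial", "stimulus", "q", "alpha",
                                  "assoc"))) |>
    tidyr::pivot_longer(c("q", "alpha", "assoc"),
                        names_to = "latent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value,
                                     colour = .data$latent)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~stimulus, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Trial", y = NULL, colour = "Latent") +
    ggplot2::theme_minimal()
}
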