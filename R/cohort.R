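#' Specify a synthetic participant cohort
#'
#' Defines labelled groups of simulated participants in a within-subject
#' two-session (placebo/drug) design with known ground-truth parameters.
#' The associability step size `eta` is anchored at the group-condition
#' means of the empirical winning model — low performers 0.33 (placebo)
#' vs 0.24 (drug); high performers 0.26 vs 0.23 — with the drug acting as
#' a within-subject shift on `eta` only. High performers get a higher
#' inverse temperature and smaller play bias; all non-`eta` parameters
#' are shared across a subject's two sessions (paired design).
#' Between-subject SDs of the step size default to three times the
#' printed standard errors of the group means, a generator convention.
#'
#' @param n_per_group Subjects per baseline-performance group.
#' @param spec Generating [model_spec()] (a hybrid model).
#' @param eta_anchor Named list of session-wise `eta` means per group.
#' @param eta_sd Named list of between-subject SDs of baseline `eta`.
#' @param group_params Named list of per-group means for the non-`eta`
#'   parameters.
#' @param param_sd Between-subject SD applied to the non-`eta`
#'   parameters.
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 30, spec = model_spec("M3"),
                        eta_anchor = list(
                          low = c(PL = 0.33, MA = 0.24),
                          high = c(PL = 0.26, MA = 0.23)),
                        eta_sd = list(low = 3 * 0.02, high = 3 * 0.01),
                        group_params = list(
                          low = c(beta = 2, play_bias = 0.2,
                                  kappa_intercept = 1.8,
                                  kappa_confirmatory = 1,
                                  kappa_modality = 0),
                          high = c(beta = 3, play_bias = 0.1,
                                   kappa_intercept = 1.4,
                                   kappa_confirmatory = 1,
                                   kappa_modality = 0)),
                        param_sd = c(beta = 0.3, play_bias = 0.1,
                                     kappa_intercept = 0.1,
                                     kappa_confirmatory = 0.15,
                                     kappa_modality = 0.1),
                        seed = NULL) {
  stopifnot(spec$uses_associability, n_per_group >= 0)
  structure(list(n_per_group = as.integer(n_per_group), spec = spec,
                 eta_anchor = eta_anchor, eta_sd = eta_sd,
                 group_params = group_params, param_sd = param_sd,
                 seed = seed),
            class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one subject's paired parameter rows (both sessions).
draw_subject_params <- function(cs, group, subject_id) {
  sp <- cs$spec
  means <- cs$group_params[[group]]
  other <- sp$param_names[sp$param_names != "eta"]
  base <- clamp(rnorm(length(other), means[other], cs$param_sd[other]),
                sp$bounds$lower[other], sp$bounds$upper[other])
  names(base) <- other
  anchors <- cs$eta_anchor[[group]]
  eta_pl <- clamp(rnorm(1, anchors["PL"], cs$eta_sd[[group]]), 0.01, 0.99)
  shift <- anchors["MA"] - anchors["PL"]   # session effect on eta only
  eta_ma <- clamp(eta_pl + shift, 0.01, 0.99)
  purrr::map_dfr(c(PL = eta_pl, MA = eta_ma) |> seq_along(), function(i) {
    session <- c("PL", "MA")[i]
    eta <- c(eta_pl, eta_ma)[i]
    tibble::as_tibble(as.list(c(base, eta = unname(eta)))) |>
      dplyr::mutate(subject = subject_id, group = group,
                    session = session, .before = 1)
  })
}

#' Generate a labelled synthetic cohort with ground truth
#'
#' Draws per-subject parameters from the cohort specification (paired
#' across sessions: the drug shifts `eta` only) and simulates every
#' subject-session on the schedule with the generating model.
#'
#' @param cohort A [cohort_spec()].
#' @param schedule Task schedule all agents play.
#' @return An `rl_cohort` list with `data` (stacked trial tibble with
#'   `subject`, `group`, `session` id columns) and `truth` (one row per
#'   subject-session: true parameters and realized `points`).
#' @export
generate_cohort <- function(cohort, schedule) {
  force(schedule)
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(cohort$seed, {
    groups <- names(cohort$eta_anchor)
    truth <- purrr::map_dfr(seq_along(groups), function(gi) {
      g <- groups[gi]
      purrr::map_dfr(seq_len(cohort$n_per_group), function(i)
        draw_subject_params(cohort, g,
                            sprintf("%s%03d", g, i)))
    })
    if (nrow(truth) == 0)
      return(structure(list(data = tibble::tibble(),
                            truth = tibble::tibble()),
                       class = "rl_cohort"))
    sp <- cohort$spec
    data <- purrr::map_dfr(seq_len(nrow(truth)), function(r) {
      row <- truth[r, ]
      params <- unlist(row[sp$param_names])
      sim <- simulate_agent(params, sp, schedule)
      dplyr::mutate(sim, subject = row$subject, group = row$group,
                    session = row$session, .before = 1)
    })
    pts <- data |>
      dplyr::group_by(.data$subject, .data$session) |>
      dplyr::summarise(points = sum(.data$points), .groups = "drop")
    truth <- dplyr::left_join(truth, pts, by = c("subject", "session"))
    truth$model <- sp$name
    structure(list(data = data, truth = truth), class = "rl_cohort")
  })
}

#' Drug-by-baseline contrasts on simulated cohorts
#'
#' Simulates paired placebo/drug cohorts and summarizes the
#' within-subject drug effect per baseline-performance group: the change
#' in late-stage accuracy on high-noise (30/70%) blocks, in late-stage
#' learning-rate variability, and in the reversal-vs-misleading
#' learning-rate contrast ([snr()]). Accuracy uses the model-implied
#' probability of a correct choice (the agent's play probability or its
#' complement), a lower-variance estimator of the same quantity as
#' sampled choices. Because a single pseudo-random schedule realization
#' modulates the contrast, the computation averages over
#' `n_realizations` independent (schedule, cohort) pairs.
#'
#' @param n_realizations Number of (schedule, cohort) realizations.
#' @param n_per_group Subjects per baseline group in each realization.
#' @param seed Base seed; realization seeds are derived from it.
#' @param split Late-stage boundary (last early position).
#' @return A tibble with one row per realization: `accuracy_low`,
#'   `accuracy_high`, `snr_low`, `lr_sd_low` (all MA minus PL).
#' @export
cohort_drug_contrasts <- function(n_realizations = 10, n_per_group = 40,
                                  seed = 1, split = 10) {
  purrr::map_dfr(seq_len(n_realizations), function(k) {
    sched <- build_schedule(task_config(seed = seed + 611 * k))
    co <- generate_cohort(cohort_spec(n_per_group = n_per_group,
                                      seed = seed + 997 * k), sched)
    d <- co$data |>
      dplyr::filter(.data$block > 1,
                    .data$trials_since_reversal > split,
                    .data$noise_level == "high") |>
      dplyr::mutate(pc = ifelse(.data$label == "good", .data$p_play,
                                1 - .data$p_play)) |>
      dplyr::group_by(.data$group, .data$session) |>
      dplyr::summarise(a = mean(.data$pc), .groups = "drop")
    g <- function(gr, se) d$a[d$group == gr & d$session == se]
    lv <- lr_variability(co$data, stage = "late", split = split,
                         by = c("subject", "group", "session")) |>
      dplyr::group_by(.data$group, .data$session) |>
      dplyr::summarise(s = mean(.data$alpha_sd), .groups = "drop")
    l <- function(gr, se) lv$s[lv$group == gr & lv$session == se]
    sn <- snr(co$data, split = split,
              by = c("subject", "group", "session")) |>
      dplyr::group_by(.data$group, .data$session) |>
      dplyr::summarise(s = mean(.data$snr, na.rm = TRUE),
                       .groups = "drop")
    s_of <- function(gr, se) sn$s[sn$group == gr & sn$session == se]
    tibble::tibble(
      realization = k,
      accuracy_low = g("low", "MA") - g("low", "PL"),
      accuracy_high = g("high", "MA") - g("high", "PL"),
      snr_low = s_of("low", "MA") - s_of("low", "PL"),
      lr_sd_low = l("low", "MA") - l("low", "PL"))
  })
}

#' Parameter- and model-recovery report
#'
#' Joins ground-truth parameters with fitted estimates and reports, per
#' parameter, the Pearson correlation, mean signed error (fit - truth)
#' and RMSE. When fits for several candidate models are supplied, a
#' model-recovery confusion matrix (generating model vs BIC-selected
#' model per subject-session) is attached.
#'
#' @param truth Ground-truth tibble from [generate_cohort()].
#' @param fits Fit table from [fit_cohort()].
#' @param id_cols Identifier columns present in both tables.
#' @return A `recovery_report` list with `parameters` (tibble) and,
#'   when applicable, `confusion` (table).
#' @export
recovery_report <- function(truth, fits,
                            id_cols = intersect(c("subject", "session"),
                                                names(truth))) {
  fitted_models <- unique(fits$model)
  gen_model <- unique(truth$model)
  stopifnot(length(gen_model) >= 1)
  same <- fits[fits$model %in% gen_model, ]
  merged <- dplyr::inner_join(truth, same, by = id_cols,
                              suffix = c("_true", "_fit"))
  if (nrow(merged) != nrow(truth))
    abort("Mismatched subject-session ids between `truth` and `fits`.")
  par_names <- model_spec(gen_model[1])$param_names
  params <- purrr::map_dfr(par_names, function(p) {
    x <- merged[[paste0(p, "_true")]]
    y <- merged[[paste0(p, "_fit")]]
    if (is.null(x)) x <- merged[[p]]
    if (is.null(y)) y <- merged[[p]]
    tibble::tibble(parameter = p,
                   r = if (sd(x) > 0 && sd(y) > 0)
                     stats::cor(x, y) else NA_real_,
                   bias = mean(y - x),
                   rmse = sqrt(mean((y - x)^2)),
                   n = length(x))
  })
  out <- list(parameters = params)
  if (length(fitted_models) > 1) {
    sel <- fits |>
      dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
      dplyr::slice_min(.data$bic, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::inner_join(truth[, c(id_cols, "model")], by = id_cols,
                        suffix = c("_selected", "_generated"))
    out$confusion <- table(generated = sel$model_generated,
                           selected = sel$model_selected)
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$parameters)
  if (!is.null(x$confusion)) {
    cat("\nModel recovery confusion:\n")
    print(x$confusion)
  }
  invisible(x)
}
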