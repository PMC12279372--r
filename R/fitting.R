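#' Fit a model to one subject's choices by MAP estimation
#'
#' Maximizes the log posterior of the observed choices (log likelihood
#' plus the log prior of [default_prior()]) with multi-start bounded
#' quasi-Newton optimization ([stats::nlminb()]). Starts are drawn
#' uniformly inside the parameter box; the best local optimum is returned.
#'
#' @param data A trial dataset (one subject-session) with `stimulus`,
#'   `action`, `outcome_valence`.
#' @param spec A [model_spec()].
#' @param n_starts Number of random starts.
#' @param seed Optional RNG seed (start points are drawn from it, making
#'   the fit deterministic).
#' @param bounds List with named `lower`/`upper` vectors; defaults to the
#'   spec's box (`beta` in \[0, 10\], `play_bias` in \[-3, 3\], kappa
#'   weights in \[-10, 10\], `eta` in \[0, 1\]).
#' @param log_prior Log-prior function; `NULL` for bounded ML.
#' @return An `rl_fit` object: MAP parameters, `log_posterior`,
#'   `log_lik` (choice log likelihood at the MAP), `n_trials`, `bic`,
#'   per-start objectives, `best_start`, and a `converged` flag (FALSE
#'   only if every start failed).
#' @export
fit_map <- function(data, spec, n_starts = 10, seed = NULL,
                    bounds = spec$bounds, log_prior = default_prior()) {
  stopifnot(nrow(data) > 0)
  lower <- bounds$lower[spec$param_names]
  upper <- bounds$upper[spec$param_names]
  obj <- function(x) {
    p <- setNames(x, spec$param_names)
    nll <- rl_choice_nll(p, spec, data)
    if (!is.null(log_prior)) nll <- nll - log_prior(p, spec)
    nll
  }
  with_seed(seed, {
    starts <- vapply(seq_len(n_starts), function(i)
      runif(spec$n_params, lower, upper), numeric(spec$n_params))
    fits <- lapply(seq_len(n_starts), function(i) {
      tryCatch(nlminb(starts[, i], obj, lower = lower, upper = upper,
                      control = list(iter.max = 500, eval.max = 1000)),
               error = function(e) NULL)
    })
  })
  # nlminb signals normal termination through code 0 or a
  # "*convergence*" message (including the conservative "false
  # convergence (8)" it emits at flat or boundary optima); only
  # iteration/evaluation-limit hits and errors count as failed starts
  start_ok <- function(f)
    f$convergence == 0 || grepl("convergence", f$message %||% "")
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    res <- list(params = setNames(rep(NA_real_, spec$n_params),
                                  spec$param_names),
                spec = spec, log_posterior = NA_real_, log_lik = NA_real_,
                n_trials = nrow(data), bic = NA_real_,
                n_starts = n_starts, best_start = NA_integer_,
                start_objectives = rep(NA_real_, n_starts),
                converged = FALSE)
    return(structure(res, class = "rl_fit"))
  }
  objs <- vapply(fits, function(f) if (is.null(f)) Inf else f$objective,
                 numeric(1))
  best <- which.min(objs)
  par <- setNames(fits[[best]]$par, spec$param_names)
  log_lik <- -rl_choice_nll(par, spec, data)
  structure(list(params = par, spec = spec,
                 log_posterior = -objs[best], log_lik = log_lik,
                 n_trials = nrow(data),
                 bic = bic_value(log_lik, spec$n_params, nrow(data)),
                 n_starts = n_starts, best_start = best,
                 start_objectives = objs,
                 converged = any(vapply(fits[ok], start_ok,
                                        logical(1)))),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("<rl_fit %s> logLik %.2f, BIC %.2f, %d trials\n",
              x$spec$name, x$log_lik, x$bic, x$n_trials))
  print(round(x$params, 4))
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * lnL` with `k` free parameters and `n` trials;
#' evaluated at the maximum-likelihood (here: MAP) point.
#'
#' @param fit An `rl_fit`, or a log likelihood when `k` and `n` are given.
#' @param k,n Number of free parameters and of trials (scalar overload).
#' @return BIC value.
#' @export
bic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "rl_fit"))
    return(bic_value(fit$log_lik, fit$spec$n_params, fit$n_trials))
  bic_value(fit, k, n)
}

bic_value <- function(log_lik, k, n) k * log(n) - 2 * log_lik

#' Fit several models to a cohort of trial datasets
#'
#' Maps [fit_map()] over every subject-session x model combination of a
#' stacked trial table. Per-fit seeds are derived deterministically from
#' `seed`.
#'
#' @param data Stacked trial tibble containing the id columns.
#' @param specs List of [model_spec()] objects (or model names).
#' @param id_cols Character vector of columns identifying one dataset.
#' @param n_starts,seed,log_prior Passed to [fit_map()].
#' @return A tibble with the id columns, `model`, one column per
#'   parameter, `log_lik`, `bic`, `converged`, and the full fit in the
#'   `fit` list-column.
#' @export
fit_cohort <- function(data, specs = list(model_spec("M3")),
                       id_cols = intersect(c("subject", "session"),
                                           names(data)),
                       n_starts = 10, seed = NULL,
                       log_prior = default_prior()) {
  if (is.character(specs)) specs <- lapply(specs, model_spec)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  groups <- dplyr::distinct(data[, id_cols, drop = FALSE])
  grid <- tidyr::expand_grid(.g = seq_len(nrow(groups)),
                             .m = seq_along(specs))
  purrr::pmap_dfr(grid, function(.g, .m) {
    ids <- groups[.g, , drop = FALSE]
    d <- dplyr::semi_join(data, ids, by = id_cols)
    sp <- specs[[.m]]
    fit_seed <- if (is.null(seed)) NULL else
      (seed + 7901L * .g + 104729L * .m) %% .Machine$integer.max
    f <- fit_map(d, sp, n_starts = n_starts, seed = fit_seed,
                 log_prior = log_prior)
    dplyr::bind_cols(ids, tibble::tibble(model = sp$name),
                     tibble::as_tibble(as.list(f$params)),
                     tibble::tibble(log_lik = f$log_lik, bic = f$bic,
                                    converged = f$converged,
                                    fit = list(f)))
  })
}

#' Model-evidence matrix from a cohort fit table
#'
#' Uses `-0.5 * BIC` as the per-subject model-evidence proxy (the Laplace
#' approximation up to a constant), or the log posterior when requested.
#'
#' @param fits Output of [fit_cohort()] with >= 2 models.
#' @param id_cols Identifier columns.
#' @param proxy `"bic"` (default) or `"log_posterior"`.
#' @return Numeric matrix (subjects x models) of log evidences.
#' @export
evidence_matrix <- function(fits,
                            id_cols = intersect(c("subject", "session"),
                                                names(fits)),
                            proxy = c("bic", "log_posterior")) {
  proxy <- match.arg(proxy)
  fits$.ev <- if (proxy == "bic") -0.5 * fits$bic else
    vapply(fits$fit, function(f) f$log_posterior, numeric(1))
  wide <- fits |>
    dplyr::mutate(.id = do.call(paste,
                                c(fits[, id_cols, drop = FALSE],
                                  sep = "/"))) |>
    dplyr::select(dplyr::all_of(c(".id", "model", ".ev"))) |>
    tidyr::pivot_wider(names_from = "model", values_from = ".ev")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$.id
  m
}

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect
#' with unknown population frequencies distributed Dirichlet(alpha). A
#' variational scheme (uniform `Dirichlet(1)` prior; iterate subject
#' responsibilities and the Dirichlet update until `max |d alpha| < tol`)
#' estimates `alpha`; exceedance probabilities (the probability that a
#' model is the most frequent) come from seeded Monte-Carlo Dirichlet
#' sampling. The Bayes omnibus risk — the posterior probability that all
#' models are equally frequent — is computed from the free energy of the
#' frequency model against the equal-frequency null, and protects the
#' exceedance probabilities: `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param log_evidence Subjects x models matrix of log model evidences
#'   (finite), e.g. from [evidence_matrix()].
#' @param alpha0 Prior Dirichlet weight per model.
#' @param tol,max_iter Convergence controls of the variational loop.
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed Optional RNG seed for the draws.
#' @return An `rl_bms` object: `alpha`, `expected_freq`, `xp`, `bor`,
#'   `pxp`, `responsibilities`.
#' @export
bms <- function(log_evidence, alpha0 = 1, tol = 1e-6, max_iter = 1e4,
                n_samples = 1e5, seed = NULL) {
  m <- as.matrix(log_evidence)
  if (!all(is.finite(m))) abort("`log_evidence` must be finite.")
  if (ncol(m) < 2) abort("Need at least two models.")
  K <- ncol(m); S <- nrow(m)
  models <- colnames(m) %||% paste0("model", seq_len(K))

  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(m, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- exp(lg - apply(lg, 1, max))
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  xp <- with_seed(seed, {
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha,
                                                      each = n_samples)),
                    nrow = n_samples)
    tabulate(max.col(draws), K) / n_samples
  })

  bor <- bms_bor(m, alpha, g, alpha0)
  pxp <- (1 - bor) * xp + bor / K

  structure(list(alpha = setNames(alpha, models),
                 expected_freq = setNames(alpha / sum(alpha), models),
                 xp = setNames(xp, models),
                 bor = bor,
                 pxp = setNames(pxp, models),
                 responsibilities = g,
                 n_subjects = S),
            class = "rl_bms")
}

# Free energy of the variational frequency model vs the equal-frequency
# null; bor = p(null | data) = 1 / (1 + exp(F1 - F0)).
bms_bor <- function(m, alpha, g, alpha0) {
  K <- ncol(m)
  a0 <- rep(alpha0, K)
  Elnr <- digamma(alpha) - digamma(sum(alpha))
  g_safe <- pmax(g, 1e-300)
  F1 <- sum(g * m) + sum(g %*% Elnr) - sum(g * log(g_safe)) +
    (lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * Elnr)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * Elnr))
  F0 <- sum(apply(m, 1, function(row) {
    mx <- max(row); mx + log(mean(exp(row - mx)))
  }))
  1 / (1 + exp(F1 - F0))
}

#' @export
print.rl_bms <- function(x, ...) {
  cat(sprintf("<rl_bms> %d subjects, %d models, BOR %.3f\n",
              x$n_subjects, length(x$alpha), x$bor))
  print(round(rbind(alpha = x$alpha, freq = x$expected_freq,
                    xp = x$xp, pxp = x$pxp), 4))
  invisible(x)
}

#' Posterior predictive simulation from a fitted subject
#'
#' Simulates `n_agents` agents at the subject's MAP parameters on a
#' schedule and returns the reversal-aligned learning curves by
#' outcome-noise level (and the stacked trial data as an attribute).
#'
#' @param fit An `rl_fit` (or a named parameter vector plus `spec`).
#' @param schedule Task schedule to replay.
#' @param n_agents Number of simulated agents.
#' @param seed Optional RNG seed.
#' @param spec Model spec when `fit` is a bare parameter vector.
#' @param window,smooth Passed to [reversal_curves()].
#' @return A `learning_curve` tibble (see [reversal_curves()]).
#' @export
posterior_predictive <- function(fit, schedule, n_agents = 100,
                                 seed = NULL, spec = NULL, window = 30,
                                 smooth = 2) {
  force(schedule)
  if (inherits(fit, "rl_fit")) { spec <- fit$spec; params <- fit$params }
  else params <- fit
  stopifnot(!is.null(spec))
  sims <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_agents), function(i)
      dplyr::mutate(simulate_agent(params, spec, schedule), agent = i))
  })
  curves <- reversal_curves(sims, window = window, smooth = smooth)
  attr(curves, "trials") <- sims
  curves
}
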