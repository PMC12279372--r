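#' Correct-choice classification
#'
#' A choice is correct when it plays a good stimulus (p > 0.5) or passes
#' a bad one (p < 0.5). Neutral (p = 0.5) stimuli have no correct answer
#' and are excluded (`NA`).
#'
#' @param data Trial tibble with `label` and `action` columns.
#' @return `data` with a logical `correct` column (`NA` for neutral).
#' @export
correct_choice <- function(data) {
  stopifnot(all(c("label", "action") %in% names(data)))
  dplyr::mutate(data, correct = dplyr::case_when(
    .data$label == "neutral" ~ NA,
    .data$label == "good" ~ .data$action == "play",
    .data$label == "bad" ~ .data$action == "pass"))
}

# Centered running mean of half-width h with shrinking windows at edges.
running_mean <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    mean(x[w], na.rm = TRUE)
  }, numeric(1))
}

#' Reversal-aligned learning curves
#'
#' Average probability of a correct choice at each position after a
#' reversal (1-based `trials_since_reversal`), split by outcome-noise
#' level and any further grouping columns, then smoothed with a +/-`smooth`
#' trial running mean (shrinking at the edges). Neutral stimuli are
#' excluded. Only positions following an actual reversal (block > 1) are
#' aligned; first-block trials are ignored.
#'
#' @param data Stacked trial tibble (simulated or logged) with `block`,
#'   `trials_since_reversal`, `label`, `action`, `noise_level`.
#' @param window Number of post-reversal positions to keep.
#' @param smooth Running-mean half-width in trials (0 = none).
#' @param by Extra grouping columns (e.g. `c("group", "session")`).
#' @return A `learning_curve` tibble: grouping columns, `noise_level`,
#'   `position`, `value` (smoothed probability correct), `raw`, `n`.
#' @export
reversal_curves <- function(data, window = 30, smooth = 2,
                            by = character()) {
  d <- correct_choice(data) |>
    dplyr::filter(.data$block > 1, !is.na(.data$correct),
                  .data$trials_since_reversal <= window)
  if (max(data$trials_since_reversal) < window)
    warn("`window` exceeds the longest block; curve truncated.")
  grp <- c(by, "noise_level")
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp)),
                    position = .data$trials_since_reversal) |>
    dplyr::summarise(raw = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grp, "position")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(value = running_mean(.data$raw, smooth)) |>
    dplyr::ungroup()
  class(out) <- c("learning_curve", class(out))
  out
}

#' Structural-break segmentation of a learning curve
#'
#' Fits segmented ordinary least squares (per-segment intercept and
#' slope) to a curve by dynamic programming over all admissible break
#' placements with a minimum segment length, and selects the number of
#' breaks by BIC over the segmented fits. With a 30-point curve and
#' minimum segment 5, between 0 and 5 breaks can be reported
#' (`floor(n / min_seg) - 1`).
#'
#' @param values Numeric curve (e.g. the `value` column of a
#'   [reversal_curves()] row set at one noise level).
#' @param min_seg Minimum segment length in trials.
#' @param max_breaks Maximum breaks to consider; defaults to
#'   `floor(length(values) / min_seg) - 1`.
#' @return A `break_result` list: `n_breaks`, `break_positions` (last
#'   index of each segment but the final one), `segments` tibble
#'   (`start`, `end`, `intercept`, `slope`, `mean`), per-candidate
#'   `criterion` values, and `flagged` when the curve is too short for
#'   any break.
#' @export
detect_breaks <- function(values, min_seg = 5, max_breaks = NULL) {
  n <- length(values)
  mb <- max(0L, as.integer(floor(n / min_seg)) - 1L)
  if (!is.null(max_breaks)) mb <- min(mb, as.integer(max_breaks))
  if (n < 2 * min_seg || mb == 0L) {
    seg <- segment_fit(values, 1L, n)
    return(structure(list(n_breaks = 0L, break_positions = integer(),
                          segments = seg, criterion = NA_real_,
                          flagged = n < 2 * min_seg),
                     class = "break_result"))
  }
  cost <- segment_cost_matrix(values, min_seg)
  # dp[m+1, j]: best RSS of fitting positions 1..j with m breaks
  dp <- matrix(Inf, nrow = mb + 1, ncol = n)
  back <- matrix(NA_integer_, nrow = mb + 1, ncol = n)
  dp[1, ] <- cost[1, ]
  for (m in seq_len(mb)) {
    first_end <- (m + 1) * min_seg
    for (j in first_end:n) {
      ks <- (m * min_seg):(j - min_seg)   # last break position candidates
      tot <- dp[m, ks] + cost[ks + 1, j]
      best <- which.min(tot)
      dp[m + 1, j] <- tot[best]
      back[m + 1, j] <- ks[best]
    }
  }
  rss <- dp[, n]
  crit <- vapply(seq_along(rss), function(i) {
    m <- i - 1L
    k <- 2 * (m + 1) + m   # segment coefficients + break positions
    n * log(pmax(rss[i], 1e-12) / n) + k * log(n)
  }, numeric(1))
  m_best <- which.min(crit) - 1L
  breaks <- integer(0)
  j <- n
  m <- m_best
  while (m > 0) {
    b <- back[m + 1, j]
    breaks <- c(b, breaks)
    j <- b
    m <- m - 1L
  }
  bounds <- c(0L, breaks, n)
  segments <- purrr::map_dfr(seq_len(length(bounds) - 1), function(i)
    segment_fit(values, bounds[i] + 1L, bounds[i + 1]))
  structure(list(n_breaks = m_best, break_positions = breaks,
                 segments = segments, criterion = crit, flagged = FALSE),
            class = "break_result")
}

# RSS of an intercept+slope fit on positions i..j, for all admissible
# (i, j) with j - i + 1 >= min_seg.
segment_cost_matrix <- function(values, min_seg) {
  n <- length(values)
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    jmin <- i + min_seg - 1L
    if (jmin > n) break
    for (j in jmin:n) cost[i, j] <- segment_rss(values, i, j)
  }
  cost
}

segment_rss <- function(values, i, j) {
  y <- values[i:j]
  x <- seq_along(y)
  if (length(y) < 2) return(0)
  fit <- stats::lm.fit(cbind(1, x), y)
  sum(fit$residuals^2)
}

segment_fit <- function(values, i, j) {
  y <- values[i:j]
  x <- i:j
  co <- if (length(y) >= 2) coef(stats::lm.fit(cbind(1, x), y))
        else c(y, 0)
  tibble::tibble(start = i, end = j, intercept = co[1], slope = co[2],
                 mean = mean(y))
}

#' @export
print.break_result <- function(x, ...) {
  cat(sprintf("<break_result> %d break(s)%s\n", x$n_breaks,
              if (length(x$break_positions))
                paste0(" at ", paste(x$break_positions, collapse = ", "))
              else ""))
  print(x$segments)
  invisible(x)
}

#' Split post-reversal positions into early and late learning stages
#'
#' Uses the (first) structural break of the group-average learning curve:
#' early = positions `1..b`, late = `b+1..window`. Degenerate cases (no
#' break, or a break at the window edge) return an empty stage and are
#' flagged.
#'
#' @param breaks A `break_result`, or an integer break position.
#' @param window Curve length.
#' @return List with integer vectors `early` and `late`, the `break`
#'   position used, and `flagged`.
#' @export
stage_split <- function(breaks, window = 30) {
  b <- if (inherits(breaks, "break_result")) {
    if (breaks$n_breaks == 0L) 0L else breaks$break_positions[1]
  } else as.integer(breaks)
  flagged <- b <= 0L || b >= window
  list(early = if (b >= 1) seq_len(min(b, window)) else integer(0),
       late = if (b < window) seq(b + 1L, window) else integer(0),
       break_position = b, flagged = flagged)
}

#' Late-stage accuracy
#'
#' Mean probability of a correct choice on post-reversal positions after
#' the stage split (default: positions 11+ of each block, i.e. the late
#' learning stage), by noise level and optional grouping columns.
#'
#' @param data Stacked trial tibble.
#' @param split Last early-stage position; late is `split + 1` onwards.
#' @param by Extra grouping columns.
#' @return Tibble with grouping columns, `noise_level`, `accuracy`, `n`.
#' @export
late_stage_accuracy <- function(data, split = 10, by = character()) {
  correct_choice(data) |>
    dplyr::filter(.data$block > 1, !is.na(.data$correct),
                  .data$trials_since_reversal > split) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "noise_level")))) |>
    dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
}

#' Per-subject variability of the trial-wise learning rate
#'
#' Standard deviation of `alpha_t` over the requested learning stage,
#' computed per subject (population SD convention: divide by n, so an
#' alpha alternating 0.2/0.4 has SD 0.1).
#'
#' @param data Trial tibble with latents (`alpha`) and
#'   `trials_since_reversal`.
#' @param stage `"all"`, `"early"` or `"late"`.
#' @param split Stage boundary (last early position).
#' @param by Grouping columns identifying a subject (and condition).
#' @return Tibble with grouping columns and `alpha_sd`.
#' @export
lr_variability <- function(data, stage = c("all", "early", "late"),
                           split = 10, by = character()) {
  stage <- match.arg(stage)
  d <- switch(stage,
    all = data,
    early = dplyr::filter(data, .data$trials_since_reversal <= split),
    late = dplyr::filter(data, .data$trials_since_reversal > split))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (length(by) == 0)
    return(tibble::tibble(stage = stage, alpha_sd = pop_sd(d$alpha)))
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(alpha_sd = pop_sd(.data$alpha), .groups = "drop") |>
    dplyr::mutate(stage = stage)
}

#' Learning-rate signal-to-noise contrast
#'
#' Contrast between learning-rate peaks that follow true reversals
#' (signal) and peaks that follow misleading feedback late in learning
#' (noise): for every reversal, the maximum `alpha` over the stimulus's
#' first `k_window` encounters of the new block; for every late-stage
#' misleading outcome, the maximum `alpha` over the same stimulus's next
#' `k_window` encounters. SNR = mean signal peak - mean noise peak. Both
#' terms shift equally under a constant added to all alphas, so the
#' contrast is location-invariant.
#'
#' @param data Trial tibble with latents, schedule columns and (if
#'   absent, added) `misleading` flags.
#' @param k_window Peak-search window in encounters after the event.
#' @param split Last early-stage position; misleading events are counted
#'   from positions `> split`.
#' @param by Grouping columns (e.g. subject).
#' @return Tibble with grouping columns, `signal`, `noise`, `snr`,
#'   event counts; `snr` is `NA` (flagged) when a group has no late
#'   misleading event.
#' @export
snr <- function(data, k_window = 5, split = 10, by = character()) {
  if (!"misleading" %in% names(data)) data <- label_misleading(data)
  groups <- if (length(by)) dplyr::group_split(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))))
  else list(data)
  purrr::map_dfr(groups, function(d) {
    ids <- d[1, by, drop = FALSE]
    per_stim <- d |>
      dplyr::arrange(.data$trial) |>
      dplyr::group_by(.data$stimulus) |>
      dplyr::group_split()
    sig <- c(); noi <- c()
    for (s in per_stim) {
      n <- nrow(s)
      rev_idx <- which(s$trials_since_reversal == 1 & s$block > 1)
      for (i in rev_idx)
        sig <- c(sig, max(s$alpha[i:min(n, i + k_window - 1)]))
      mis_idx <- which(s$misleading & s$trials_since_reversal > split)
      mis_idx <- mis_idx[mis_idx < n]
      for (i in mis_idx)
        noi <- c(noi, max(s$alpha[(i + 1):min(n, i + k_window)]))
    }
    dplyr::bind_cols(ids, tibble::tibble(
      signal = if (length(sig)) mean(sig) else NA_real_,
      noise = if (length(noi)) mean(noi) else NA_real_,
      n_reversals = length(sig), n_misleading = length(noi),
      snr = if (length(sig) && length(noi)) mean(sig) - mean(noi)
            else NA_real_))
  })
}

#' Accuracy after two consecutive misleading feedbacks
#'
#' Restricted to high-noise (30/70%) stimuli and the late learning stage:
#' finds runs of two consecutive misleading outcomes on the same stimulus
#' within a block and reports the probability that the next encounter of
#' that stimulus (still within the block) is a correct choice.
#'
#' @inheritParams snr
#' @return Tibble with grouping columns, `n_events` and `accuracy`
#'   (`NA`, flagged, when no qualifying event exists).
#' @export
double_misleading_accuracy <- function(data, split = 10,
                                       by = character()) {
  if (!"misleading" %in% names(data)) data <- label_misleading(data)
  data <- correct_choice(data)
  groups <- if (length(by)) dplyr::group_split(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))))
  else list(data)
  purrr::map_dfr(groups, function(d) {
    ids <- d[1, by, drop = FALSE]
    events <- d |>
      dplyr::filter(.data$noise_level == "high") |>
      dplyr::arrange(.data$trial) |>
      dplyr::group_by(.data$stimulus, .data$block) |>
      dplyr::filter(dplyr::n() >= 3) |>
      dplyr::mutate(
        hit = .data$misleading & dplyr::lag(.data$misleading) &
          .data$trials_since_reversal > split &
          dplyr::lag(.data$trials_since_reversal) > split,
        next_correct = dplyr::lead(.data$correct)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$hit, !is.na(.data$next_correct))
    dplyr::bind_cols(ids, tibble::tibble(
      n_events = nrow(events),
      accuracy = if (nrow(events)) mean(events$next_correct)
                 else NA_real_))
  })
}

#' Regress task performance on model parameters
#'
#' Ordinary least squares of a per-subject performance score (total
#' points) on z-scored parameter estimates, with intercept and
#' normal-theory 95% confidence intervals. Standardized predictors make
#' the coefficients directly comparable.
#'
#' @param params Tibble/data frame of per-subject parameter estimates
#'   (numeric columns only are used).
#' @param scores Numeric vector of performance scores, aligned with the
#'   rows of `params`.
#' @param conf_level Confidence level for the intervals.
#' @return Tibble with `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @export
performance_glm <- function(params, scores, conf_level = 0.95) {
  x <- dplyr::select(tibble::as_tibble(params),
                     dplyr::where(is.numeric))
  stopifnot(nrow(x) == length(scores))
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    abort(sprintf("Constant predictor column(s): %s",
                  paste(names(x)[sds == 0], collapse = ", ")))
  z <- as.data.frame(scale(x))
  qr_rank <- qr(as.matrix(z))$rank
  if (qr_rank < ncol(z)) {
    drop_idx <- qr(as.matrix(z))$pivot[seq(qr_rank + 1, ncol(z))]
    abort(sprintf("Collinear predictor column(s): %s",
                  paste(names(z)[drop_idx], collapse = ", ")))
  }
  fit <- lm(scores ~ ., data = cbind(scores = scores, z))
  ci <- confint(fit, level = conf_level)
  est <- summary(fit)$coefficients
  tibble::tibble(term = rownames(est), estimate = est[, 1],
                 std_error = est[, 2], conf_low = ci[, 1],
                 conf_high = ci[, 2])
}

#' Performance as a function of the associability step size
#'
#' Simulates cohorts of hybrid-model agents that differ only in `eta`
#' and records the mean total points per `eta` value — the simulation
#' behind the inverted-U relation between learning-rate flexibility and
#' payoff, where the highest step sizes perform particularly poorly.
#'
#' @param base_params Named parameter vector; its `eta` entry is swept.
#' @param spec A hybrid [model_spec()] (M2-M4).
#' @param schedule Task schedule.
#' @param eta_grid Numeric vector of step sizes in `[0, 1]`.
#' @param n_agents Agents per grid point.
#' @param seed Optional RNG seed.
#' @return An `eta_sweep` tibble: `eta`, `mean_points`, `se_points`,
#'   `n_agents`; the grid argmax is in `attr(, "best_eta")`.
#' @export
eta_sweep <- function(base_params, spec, schedule,
                      eta_grid = seq(0.05, 0.95, by = 0.1),
                      n_agents = 1000, seed = NULL) {
  force(base_params); force(schedule); force(eta_grid)
  stopifnot(spec$uses_associability,
            all(eta_grid >= 0 & eta_grid <= 1))
  ppo <- attr(schedule, "task_config")$points_per_outcome %||% 10
  out <- with_seed(seed, {
    purrr::map_dfr(eta_grid, function(e) {
      p <- base_params
      p["eta"] <- e
      pts <- vapply(seq_len(n_agents), function(i) {
        res <- rl_engine(p, spec, schedule)
        r <- ifelse(schedule$outcome_valence == "win", 1, -1)
        ppo * sum(r[res$action == 1])
      }, numeric(1))
      tibble::tibble(eta = e, mean_points = mean(pts),
                     se_points = sd(pts) / sqrt(n_agents),
                     n_agents = n_agents)
    })
  })
  attr(out, "best_eta") <- out$eta[which.max(out$mean_points)]
  class(out) <- c("eta_sweep", class(out))
  out
}
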