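#' Task configuration for the probabilistic reversal-learning task
#'
#' Describes the blocked reversal design: each of `n_stimuli` stimuli runs
#' through `blocks_per_stimulus` blocks of constant reward contingency; at
#' every block boundary the contingency changes without notice (a reversal).
#' Contingencies are drawn from `probability_levels`, which induce three
#' outcome-noise regimes: low (20/80%), high (30/70%) and random (50%).
#' The defaults reproduce the canonical design: 3 stimuli x 7 blocks of
#' 30-35 trials each, 714 trials and 18 reversals in total.
#'
#' @param n_stimuli Number of interleaved stimuli.
#' @param blocks_per_stimulus Number of constant-contingency blocks per
#'   stimulus; reversals per stimulus is this minus one.
#' @param block_length_range Integer pair; every block length (counted in
#'   encounters of that stimulus) lies in this inclusive range.
#' @param total_trials Total trial count; must be divisible by `n_stimuli`
#'   and attainable as a sum of block lengths within the range.
#' @param probability_levels Admissible reward probabilities.
#' @param points_per_outcome Points won or lost on a played trial.
#' @param seed Optional RNG seed making the schedule reproducible.
#' @return A `task_config` list.
#' @export
#' @examples
#' cfg <- task_config(seed = 1)
#' sched <- build_schedule(cfg)
#' nrow(sched)
task_config <- function(n_stimuli = 3, blocks_per_stimulus = 7,
                        block_length_range = c(30L, 35L),
                        total_trials = 714,
                        probability_levels = c(0.2, 0.3, 0.5, 0.7, 0.8),
                        points_per_outcome = 10, seed = NULL) {
  stopifnot(n_stimuli >= 1, blocks_per_stimulus >= 1,
            length(block_length_range) == 2,
            block_length_range[1] <= block_length_range[2],
            all(probability_levels >= 0 & probability_levels <= 1))
  if (total_trials %% n_stimuli != 0)
    abort("`total_trials` must be divisible by `n_stimuli`.")
  per_stim <- total_trials / n_stimuli
  lo <- blocks_per_stimulus * block_length_range[1]
  hi <- blocks_per_stimulus * block_length_range[2]
  if (per_stim < lo || per_stim > hi)
    abort(sprintf(paste0("Infeasible configuration: %d trials per stimulus ",
                         "cannot be partitioned into %d blocks of length ",
                         "%d-%d."), per_stim, blocks_per_stimulus,
                  block_length_range[1], block_length_range[2]))
  structure(list(n_stimuli = as.integer(n_stimuli),
                 blocks_per_stimulus = as.integer(blocks_per_stimulus),
                 block_length_range = as.integer(block_length_range),
                 total_trials = as.integer(total_trials),
                 probability_levels = probability_levels,
                 points_per_outcome = points_per_outcome,
                 seed = seed),
            class = "task_config")
}

# Block lengths within [lo, hi] summing to `total`: rejection sampling with
# a constructive fallback (distribute the excess over min one unit at a
# time among blocks with spare capacity).
sample_block_lengths <- function(n_blocks, lo, hi, total, max_tries = 2000) {
  if (lo == hi) return(rep(lo, n_blocks))
  for (i in seq_len(max_tries)) {
    len <- sample(lo:hi, n_blocks, replace = TRUE)
    if (sum(len) == total) return(len)
  }
  len <- rep(lo, n_blocks)
  excess <- total - sum(len)
  while (excess > 0) {
    open <- which(len < hi)
    pick <- open[sample.int(length(open), 1)]
    len[pick] <- len[pick] + 1L
    excess <- excess - 1L
  }
  len
}

# A per-stimulus contingency sequence: consecutive blocks differ, and when
# the level set allows it the sequence visits both a "good" (>0.5) and a
# "bad" (<0.5) level so every stimulus has phases on both sides of chance.
sample_prob_sequence <- function(n_blocks, levels, max_tries = 1000) {
  need_both <- any(levels > 0.5) && any(levels < 0.5) && n_blocks >= 2
  for (i in seq_len(max_tries)) {
    p <- numeric(n_blocks)
    p[1] <- sample(levels, 1)
    if (n_blocks > 1)
      for (b in 2:n_blocks) p[b] <- sample(setdiff(levels, p[b - 1]), 1)
    if (!need_both || (any(p > 0.5) && any(p < 0.5))) return(p)
  }
  abort("Could not draw a contingency sequence; check `probability_levels`.")
}

# Counterbalanced contingency assignment across the whole schedule: every
# level is used a comparable number of times and good (>0.5) and bad
# (<0.5) blocks are matched, emulating a deliberately balanced design.
# Falls back to the last draw if the constraints cannot be met.
sample_balanced_sequences <- function(n_stimuli, n_blocks, levels,
                                      max_tries = 500) {
  n_total <- n_stimuli * n_blocks
  per_level <- n_total / length(levels)
  lo <- max(0, floor(per_level) - 1)
  hi <- ceiling(per_level) + 1
  check_balance <- length(levels) > 1 && per_level >= 1
  probs <- NULL
  for (i in seq_len(max_tries)) {
    probs <- lapply(seq_len(n_stimuli), function(s)
      sample_prob_sequence(n_blocks, levels))
    if (!check_balance) return(probs)
    all_p <- unlist(probs)
    counts <- vapply(levels, function(l) sum(all_p == l), numeric(1))
    if (all(counts >= lo & counts <= hi) &&
        abs(sum(all_p > 0.5) - sum(all_p < 0.5)) <= 2)
      return(probs)
  }
  probs
}

noise_label <- function(p) {
  dplyr::case_when(p == 0.5 ~ "random",
                   p %in% c(0.3, 0.7) ~ "high",
                   p %in% c(0.2, 0.8) ~ "low",
                   abs(p - 0.5) < 0.15 ~ "random",
                   abs(p - 0.5) < 0.35 ~ "high",
                   TRUE ~ "low")
}

#' Build a reversal-learning task schedule
#'
#' Generates the trial-by-trial design: an interleaved pseudo-random
#' stimulus sequence (stimuli are presented in shuffled consecutive
#' "rounds", so no stimulus is absent for more than `2 * n_stimuli - 2`
#' trials), per-stimulus block lengths drawn from the configured range under
#' the total-trial constraint, per-block reward contingencies with forced
#' change at every boundary, and pre-drawn Bernoulli outcome valences.
#' Outcome valences are drawn once per trial independent of any agent's
#' action: factual feedback (on play) and counterfactual feedback (on pass)
#' are two views of the same draw.
#'
#' @param config A [task_config()].
#' @return A tibble with one row per trial and columns `trial`, `stimulus`,
#'   `block`, `trials_since_reversal` (1-based encounter index within the
#'   current block), `p_reward`, `noise_level` (`"low"`/`"high"`/`"random"`),
#'   `label` (`"good"`, `"bad"` or `"neutral"` by `p_reward` vs 0.5) and
#'   `outcome_valence` (`"win"`/`"loss"`).
#' @export
build_schedule <- function(config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  with_seed(config$seed, {
    ns <- config$n_stimuli
    per_stim <- config$total_trials / ns
    lens <- lapply(seq_len(ns), function(s)
      sample_block_lengths(config$blocks_per_stimulus,
                           config$block_length_range[1],
                           config$block_length_range[2], per_stim))
    probs <- sample_balanced_sequences(ns, config$blocks_per_stimulus,
                                       config$probability_levels)
    # interleaving: each consecutive round presents all stimuli in random order
    stim_seq <- as.vector(vapply(seq_len(per_stim),
                                 function(r) sample.int(ns), integer(ns)))
    enc <- integer(ns)  # running encounter count per stimulus
    block <- integer(config$total_trials)
    tsr <- integer(config$total_trials)
    p_reward <- numeric(config$total_trials)
    for (t in seq_len(config$total_trials)) {
      s <- stim_seq[t]
      enc[s] <- enc[s] + 1L
      b <- findInterval(enc[s] - 1L, cumsum(lens[[s]])) + 1L
      block[t] <- b
      tsr[t] <- enc[s] - c(0L, cumsum(lens[[s]]))[b]
      p_reward[t] <- probs[[s]][b]
    }
    sched <- tibble::tibble(
      trial = seq_len(config$total_trials),
      stimulus = stim_seq,
      block = block,
      trials_since_reversal = tsr,
      p_reward = p_reward,
      noise_level = noise_label(p_reward),
      label = dplyr::case_when(p_reward > 0.5 ~ "good",
                               p_reward < 0.5 ~ "bad",
                               TRUE ~ "neutral"),
      outcome_valence = NA_character_)
    attr(sched, "task_config") <- config
    draw_outcomes(sched)
  })
}

#' Draw per-trial outcome valences
#'
#' Fills (or redraws) `outcome_valence` with independent Bernoulli draws at
#' each trial's `p_reward`. Valences are action-independent: the same draw
#' is shown as factual feedback after a play and as fictive feedback after
#' a pass.
#'
#' @param schedule A schedule tibble with a `p_reward` column.
#' @param seed Optional RNG seed.
#' @return The schedule with `outcome_valence` set to `"win"`/`"loss"`.
#' @export
draw_outcomes <- function(schedule, seed = NULL) {
  force(schedule)
  stopifnot("p_reward" %in% names(schedule))
  with_seed(seed, {
    schedule$outcome_valence <-
      ifelse(runif(nrow(schedule)) < schedule$p_reward, "win", "loss")
    schedule
  })
}

#' Flag misleading (probabilistic) feedback
#'
#' A trial's feedback is misleading when it contradicts the stimulus's
#' underlying label: a win for a bad (p < 0.5) stimulus or a loss for a
#' good (p > 0.5) stimulus. Neutral (p = 0.5) stimuli are never flagged.
#'
#' @param schedule A schedule (or trial dataset) with `label` and
#'   `outcome_valence` columns.
#' @return The input with a logical `misleading` column added.
#' @export
label_misleading <- function(schedule) {
  stopifnot(all(c("label", "outcome_valence") %in% names(schedule)))
  dplyr::mutate(schedule, misleading =
    (.data$label == "good" & .data$outcome_valence == "loss") |
    (.data$label == "bad" & .data$outcome_valence == "win"))
}

#' The canonical task schedule
#'
#' A fixed realization of the default design (3 stimuli x 7 blocks of
#' 30-35 trials, 714 trials, 18 reversals, counterbalanced
#' contingencies), shipped as a plain-CSV fixture built from the
#' documented seed 714. It plays the role of the fixed pseudo-random
#' series all participants saw: an emulation of that series, not a
#' reconstruction.
#'
#' @return The canonical schedule tibble (with misleading-feedback
#'   flags).
#' @export
#' @examples
#' nrow(canonical_task_schedule())
canonical_task_schedule <- function() {
  path <- system.file("extdata", "canonical_schedule.csv",
                      package = "revlearn")
  if (nzchar(path)) label_misleading(read_schedule(path))
  else label_misleading(build_schedule(task_config(seed = 714)))
}

#' Count reversals in a schedule
#'
#' A reversal is a same-stimulus contingency change, i.e. the first
#' encounter of every block after a stimulus's first.
#'
#' @param schedule A schedule tibble.
#' @return Integer reversal count.
#' @export
count_reversals <- function(schedule) {
  schedule |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::summarise(rev = sum(diff(.data$p_reward) != 0),
                     .groups = "drop") |>
    dplyr::pull(.data$rev) |>
    sum() |>
    as.integer()
}

schedule_columns <- c("trial", "stimulus", "block", "trials_since_reversal",
                      "p_reward", "noise_level", "label", "outcome_valence")

#' Read and write schedules and trial datasets
#'
#' Schedules and trial-level datasets are stored as plain CSV with a
#' one-line header. A schedule carries the eight design columns; a trial
#' dataset adds the agent's `action`, feedback `modality`, `confirmatory`
#' flag and internal reward signal `R` (plus any latent columns present).
#' Reading restores column types so that a write/read round trip is
#' lossless.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_schedule()`/`read_trials()` return a tibble;
#'   the writers return `x` invisibly.
#' @export
write_schedule <- function(x, path) {
  readr::write_csv(x[, intersect(c(schedule_columns, "misleading"),
                                 names(x))], path)
  invisible(x)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial = "i", stimulus = "i", block = "i",
                    trials_since_reversal = "i", p_reward = "d",
                    noise_level = "c", label = "c", outcome_valence = "c",
                    .default = readr::col_guess()))
}

#' @rdname write_schedule
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname write_schedule
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial = "i", stimulus = "i", block = "i",
                    trials_since_reversal = "i", p_reward = "d",
                    noise_level = "c", label = "c", outcome_valence = "c",
                    action = "c", modality = "c", confirmatory = "l",
                    R = "d", .default = readr::col_guess()))
}
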