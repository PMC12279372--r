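# Shared fixtures, all generated in code.

# Canonical full-size schedule, built once per test run.
canonical_schedule <- local({
  sched <- NULL
  function() {
    if (is.null(sched)) sched <<- build_schedule(task_config(seed = 20260928))
    sched
  }
})

# A tiny one-stimulus schedule (8 trials, 2 blocks of 4) for enumeration
# oracles.
toy_schedule <- function(seed = 1, p_levels = c(0.2, 0.8)) {
  build_schedule(task_config(n_stimuli = 1, blocks_per_stimulus = 2,
                             block_length_range = c(4, 4),
                             total_trials = 8,
                             probability_levels = p_levels, seed = seed))
}

m3_params <- function(beta = 2, play_bias = 0.2, kappa_intercept = 1.8,
                      kappa_confirmatory = 1, eta = 0.3) {
  agent_params(beta = beta, play_bias = play_bias,
               kappa_intercept = kappa_intercept,
               kappa_confirmatory = kappa_confirmatory, eta = eta,
               spec = model_spec("M3"))
}

# Independent brute-force oracle for segmented least squares: enumerate
# every admissible break placement for m breaks and minimize RSS.
brute_force_breaks <- function(values, min_seg = 5) {
  n <- length(values)
  seg_rss <- function(i, j) {
    y <- values[i:j]; x <- i:j
    sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  }
  mb <- max(0L, floor(n / min_seg) - 1L)
  best <- vector("list", mb + 1)
  best[[1]] <- list(rss = seg_rss(1, n), breaks = integer(0))
  if (mb >= 1) {
    for (m in seq_len(mb)) {
      combos <- utils::combn(seq_len(n - 1), m, simplify = FALSE)
      ok <- Filter(function(b) all(diff(c(0, b, n)) >= min_seg), combos)
      res <- lapply(ok, function(b) {
        bounds <- c(0, b, n)
        rss <- sum(vapply(seq_len(m + 1), function(k)
          seg_rss(bounds[k] + 1, bounds[k + 1]), numeric(1)))
        list(rss = rss, breaks = b)
      })
      best[[m + 1]] <- res[[which.min(vapply(res, `[[`, numeric(1),
                                             "rss"))]]
    }
  }
  crit <- vapply(seq_along(best), function(i) {
    m <- i - 1
    k <- 2 * (m + 1) + m
    n * log(max(best[[i]]$rss, 1e-12) / n) + k * log(n)
  }, numeric(1))
  m_sel <- which.min(crit) - 1L
  list(n_breaks = m_sel, break_positions = best[[m_sel + 1]]$breaks,
       rss_by_m = vapply(best, `[[`, numeric(1), "rss"))
}
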