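test_that("correct choices are defined by label and action", {
  d <- tibble::tibble(label = c("good", "good", "bad", "bad", "neutral"),
                      action = c("play", "pass", "pass", "play", "play"))
  expect_equal(correct_choice(d)$correct, c(TRUE, FALSE, TRUE, FALSE, NA))
})

test_that("reversal curves recover known agents", {
  sched <- canonical_schedule()
  # oracle agent: always chooses correctly from position 1
  perfect <- dplyr::mutate(sched, action = ifelse(label == "good", "play",
                                                  "pass"))
  cv <- reversal_curves(perfect, smooth = 0)
  expect_true(all(cv$value == 1))
  expect_true(all(cv$position >= 1 & cv$position <= 30))

  # random agent sits at chance
  p0 <- agent_params(beta = 0, play_bias = 0, kappa_intercept = 0,
                     eta = 0.3, spec = model_spec("M2"))
  sims <- purrr::map_dfr(1:15, function(i)
    simulate_agent(p0, model_spec("M2"), sched, seed = i))
  cv0 <- reversal_curves(sims)
  expect_true(all(abs(cv0$value - 0.5) < 0.07))
  expect_true(all(cv0$value >= 0 & cv0$value <= 1))
})

test_that("running-average smoothing shrinks at the edges", {
  x <- c(1, 2, 3, 4, 5)
  d <- tibble::tibble(block = 2, trials_since_reversal = 1:5,
                      label = "good",
                      action = rep(c("play", "pass"), length.out = 5),
                      noise_level = "high")
  # direct check through a constant curve: smoothing leaves it unchanged
  perfect <- dplyr::mutate(d, action = "play")
  cv <- reversal_curves(perfect, window = 5, smooth = 2)
  expect_true(all(cv$value == 1))
})

test_that("segmented least squares matches brute-force enumeration", {
  set.seed(1)
  for (n in c(12, 20, 30)) {
    for (rep in 1:3) {
      y <- cumsum(rnorm(n, 0, 0.3)) + rep(c(0, 2), each = n / 2)
      res <- detect_breaks(y, min_seg = 5)
      oracle <- brute_force_breaks(y, min_seg = 5)
      expect_equal(res$n_breaks, oracle$n_breaks)
      expect_equal(res$break_positions, oracle$break_positions)
    }
  }
})

test_that("break detection localizes a constructed step and resists noise", {
  set.seed(2)
  step <- c(rep(0, 10), rep(3, 20)) + rnorm(30, 0, 0.1)
  res <- detect_breaks(step, min_seg = 5)
  expect_equal(res$n_breaks, 1)
  expect_lte(abs(res$break_positions[1] - 10), 1)

  flat <- rnorm(30, 0.7, 0.02)
  expect_equal(detect_breaks(flat, min_seg = 5)$n_breaks, 0)

  # maximum reportable breaks for 30 points at segment length 5 is 5
  expect_equal(length(detect_breaks(step, min_seg = 5)$criterion) - 1, 5)

  short <- detect_breaks(rnorm(6), min_seg = 5)
  expect_equal(short$n_breaks, 0)
  expect_true(short$flagged)
})

test_that("stage split follows the break position with flagged edges", {
  s <- stage_split(10, window = 30)
  expect_equal(s$early, 1:10)
  expect_equal(s$late, 11:30)
  expect_false(s$flagged)

  s0 <- stage_split(0, window = 30)
  expect_equal(s0$early, integer(0))
  expect_equal(s0$late, 1:30)
  expect_true(s0$flagged)

  sw <- stage_split(30, window = 30)
  expect_equal(sw$late, integer(0))
  expect_true(sw$flagged)
})

test_that("learning-rate variability uses the population SD", {
  d1 <- tibble::tibble(alpha = rep(0.3, 50), trials_since_reversal = 1:50)
  expect_equal(lr_variability(d1)$alpha_sd, 0)
  d2 <- tibble::tibble(alpha = rep(c(0.2, 0.4), 25),
                       trials_since_reversal = 1:50)
  expect_equal(lr_variability(d2)$alpha_sd, 0.1)
  expect_equal(lr_variability(d2, stage = "early", split = 10)$alpha_sd,
               0.1)
})

test_that("the SNR contrast responds to constructed latent structure", {
  sched <- canonical_schedule()
  base <- dplyr::mutate(label_misleading(sched), action = "play",
                        alpha = 0.3)
  # constant learning rate: zero contrast
  r0 <- snr(base)
  expect_equal(r0$snr, 0)

  # alpha spikes only after reversals: positive contrast
  spiked <- dplyr::group_by(base, stimulus) |>
    dplyr::arrange(trial, .by_group = TRUE) |>
    dplyr::mutate(alpha = ifelse(trials_since_reversal <= 3 & block > 1,
                                 0.9, 0.1)) |>
    dplyr::ungroup()
  expect_gt(snr(spiked)$snr, 0)

  # location invariance: adding a constant to all alphas changes nothing
  shifted <- dplyr::mutate(spiked, alpha = alpha + 0.05)
  expect_equal(snr(shifted)$snr, snr(spiked)$snr, tolerance = 1e-12)
})

test_that("double-misleading accuracy matches a static agent's accuracy", {
  sched <- canonical_schedule()
  # a policy-blind coin-flip agent: conditional accuracy after any
  # feedback history equals its marginal accuracy of 1/2
  set.seed(12)
  coin <- dplyr::mutate(sched,
                        action = sample(c("play", "pass"), dplyr::n(),
                                        replace = TRUE))
  res <- double_misleading_accuracy(coin)
  expect_gt(res$n_events, 10)
  expect_lt(abs(res$accuracy - 0.5), 3 * 0.5 / sqrt(res$n_events))

  # no qualifying events is flagged as NA
  empty <- double_misleading_accuracy(head(coin, 5))
  expect_true(is.na(empty$accuracy))
})

test_that("win-stay lose-shift fails after double misleading losses", {
  # constructed high-noise block: good stimulus, two misleading losses
  # late in the block, then a win trial
  d <- tibble::tibble(
    trial = 1:14, stimulus = 1, block = 2,
    trials_since_reversal = 1:14, p_reward = 0.7, noise_level = "high",
    label = "good",
    outcome_valence = c(rep("win", 11), "loss", "loss", "win"))
  # lose-shift: passes on the trial after each loss
  d$action <- c(rep("play", 12), "pass", "pass")
  res <- double_misleading_accuracy(d)
  expect_equal(res$n_events, 1)
  expect_equal(res$accuracy, 0)
})

test_that("performance regression recovers constructed coefficients", {
  set.seed(3)
  params <- tibble::tibble(beta = runif(40, 0.5, 3),
                           eta = runif(40, 0, 1),
                           play_bias = rnorm(40))
  # constant scores: all slopes zero (the perfect fit makes lm warn)
  r0 <- suppressWarnings(performance_glm(params, rep(5, 40)))
  expect_true(all(abs(r0$estimate[-1]) < 1e-10))

  # scores exactly 2 * beta: beta coefficient is 2 * sd(beta), others 0
  r1 <- suppressWarnings(performance_glm(params, 2 * params$beta))
  expect_equal(unname(r1$estimate[r1$term == "beta"]),
               2 * sd(params$beta), tolerance = 1e-8)
  expect_lt(max(abs(r1$estimate[!r1$term %in%
                                  c("(Intercept)", "beta")])), 1e-8)
  expect_true(all(r1$conf_low <= r1$estimate &
                    r1$estimate <= r1$conf_high))

  dup <- dplyr::mutate(params, beta2 = beta)
  expect_error(performance_glm(dup, rnorm(40)), "Collinear")
  expect_error(performance_glm(dplyr::mutate(params, z = 1), rnorm(40)),
               "Constant")
})

test_that("eta sweeps are reproducible and tagged with their argmax", {
  sched <- canonical_schedule()
  base <- m3_params()
  s1 <- eta_sweep(base, model_spec("M3"), sched, eta_grid = c(0.1, 0.9),
                  n_agents = 25, seed = 4)
  s2 <- eta_sweep(base, model_spec("M3"), sched, eta_grid = c(0.1, 0.9),
                  n_agents = 25, seed = 4)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_true(attr(s1, "best_eta") %in% s1$eta)
  expect_equal(s1$n_agents, c(25, 25))
})
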