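test_that("feedback is classified by action and valence", {
  out <- classify_feedback(c("play", "pass", "play", "pass"),
                           c("win", "loss", "loss", "win"))
  expect_equal(out$modality, c("factual", "counterfactual", "factual",
                               "counterfactual"))
  expect_equal(out$confirmatory, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("model specs encode the nesting structure", {
  expect_equal(model_spec("M1")$n_params, 3)
  expect_equal(model_spec("M2")$n_params, 4)
  expect_equal(model_spec("M3")$n_params, 5)
  expect_equal(model_spec("M4")$n_params, 6)
  expect_false(model_spec("M1")$uses_associability)
  expect_equal(model_spec("M4")$kappa_predictors,
               c("intercept", "confirmatory", "modality"))
})

test_that("model primitives match their closed forms", {
  # logistic learning-rate scale
  expect_equal(kappa_scale(c(0, 0), cbind(1, c(-1, 1))), c(0.5, 0.5))
  expect_equal(kappa_scale(c(0, 1), cbind(1, 1)), plogis(1))
  expect_gt(kappa_scale(50, matrix(1)), 1 - 1e-10)
  expect_error(kappa_scale(c(1, 2), matrix(1)), "match")

  # associability update
  expect_equal(update_associability(0.4, 5, 0), 0.4)
  expect_equal(update_associability(0.4, -0.7, 1), 0.7)
  expect_equal(update_associability(0.5, 1, 0.3), 0.65)

  # value update
  uv <- update_value(0, 0.5, 1)
  expect_equal(uv$delta, 1)
  expect_equal(uv$Q, 0.5)
  expect_equal(update_value(0.3, 0, -1)$Q, 0.3)
  expect_equal(update_value(1, 0.7, 1)$Q, 1)

  # softmax with pass value 0
  expect_equal(choice_probability(0.9, 0, 0), 0.5)
  expect_equal(choice_probability(0, 0, 5), 0.5)
  expect_equal(choice_probability(0.5, 0, 2), 1 / (1 + exp(-1)))
})

test_that("engine recursion matches an independent R implementation", {
  sched <- head(canonical_schedule(), 60)
  spec <- model_spec("M4")
  params <- agent_params(beta = 1.7, play_bias = -0.3,
                         kappa_intercept = 0.4, kappa_confirmatory = 0.8,
                         kappa_modality = -0.5, eta = 0.35, spec = spec)
  sim <- simulate_agent(params, spec, sched, seed = 11)

  # replay with the exported primitives
  ns <- max(sched$stimulus)
  Q <- numeric(ns); A <- rep(1, ns)
  for (t in seq_len(nrow(sched))) {
    j <- sim$stimulus[t]
    expect_equal(sim$p_play[t],
                 choice_probability(Q[j], params["play_bias"],
                                    params["beta"]),
                 ignore_attr = TRUE)
    fb <- classify_feedback(sim$action[t], sim$outcome_valence[t])
    expect_equal(sim$modality[t], fb$modality)
    expect_equal(sim$confirmatory[t], fb$confirmatory)
    kap <- kappa_scale(params[c("kappa_intercept", "kappa_confirmatory",
                                "kappa_modality")],
                       c(1, ifelse(fb$confirmatory, 0.5, -0.5),
                         ifelse(fb$modality == "factual", 0.5, -0.5)))
    alpha <- kap * A[j]
    expect_equal(sim$alpha[t], unname(alpha))
    uv <- update_value(Q[j], alpha, sim$R[t])
    expect_equal(sim$delta[t], unname(uv$delta))
    Q[j] <- uv$Q
    A[j] <- update_associability(A[j], uv$delta, params["eta"])
  }
})

test_that("simulate-then-score reproduces the stored latents exactly", {
  sched <- canonical_schedule()
  for (name in c("M1", "M3", "M4")) {
    spec <- model_spec(name)
    params <- agent_params(beta = 2, play_bias = 0.1,
                           kappa_intercept = 1,
                           kappa_confirmatory = 0.8, kappa_modality = 0.3,
                           eta = 0.4, spec = spec)
    sim <- simulate_agent(params, spec, sched, seed = 3)
    lat <- rl_latents(params, spec, sim)
    expect_identical(lat$q, sim$q)
    expect_identical(lat$alpha, sim$alpha)
    expect_identical(lat$assoc, sim$assoc)
    expect_identical(lat$p_play, sim$p_play)
  }
})

test_that("the model family is properly nested", {
  sched <- canonical_schedule()
  sim <- simulate_agent(m3_params(), model_spec("M3"), sched, seed = 8)

  # M3 with zero confirmatory weight equals M2
  p3 <- agent_params(beta = 1.5, play_bias = 0.2, kappa_intercept = 0.7,
                     kappa_confirmatory = 0, eta = 0.3,
                     spec = model_spec("M3"))
  p2 <- agent_params(beta = 1.5, play_bias = 0.2, kappa_intercept = 0.7,
                     eta = 0.3, spec = model_spec("M2"))
  expect_equal(negative_log_posterior(p3, model_spec("M3"), sim,
                                      log_prior = NULL),
               negative_log_posterior(p2, model_spec("M2"), sim,
                                      log_prior = NULL))

  # M2 with eta = 0 keeps A at its initial value 1, matching constant-rate M1
  p2z <- agent_params(beta = 1.5, play_bias = 0.2, kappa_intercept = 0.7,
                      eta = 0, spec = model_spec("M2"))
  p1 <- agent_params(beta = 1.5, play_bias = 0.2, kappa_intercept = 0.7,
                     spec = model_spec("M1"))
  expect_equal(negative_log_posterior(p2z, model_spec("M2"), sim,
                                      log_prior = NULL),
               negative_log_posterior(p1, model_spec("M1"), sim,
                                      log_prior = NULL))

  # eta = 0 hybrid has a constant learning rate within feedback type
  lat <- rl_latents(p2z, model_spec("M2"), sim)
  expect_equal(length(unique(round(lat$alpha, 12))), 1)
})

test_that("play probability is monotone in the play bias", {
  for (Q in c(-0.5, 0, 0.8)) for (beta in c(0.5, 2)) {
    p <- choice_probability(Q, seq(-3, 3, by = 0.5), beta)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("choice likelihood is a normalized distribution over sequences", {
  sched <- toy_schedule(seed = 2)
  spec <- model_spec("M3")
  params <- agent_params(beta = 1.3, play_bias = -0.4,
                         kappa_intercept = 0.6, kappa_confirmatory = 1.1,
                         eta = 0.45, spec = spec)
  seqs <- expand.grid(rep(list(c("play", "pass")), 8),
                      stringsAsFactors = FALSE)
  total <- sum(apply(seqs, 1, function(acts) {
    d <- sched
    d$action <- unname(acts)
    exp(-negative_log_posterior(params, spec, d, log_prior = NULL))
  }))
  expect_equal(total, 1, tolerance = 1e-10)
})

test_that("degenerate parameter regimes behave as expected", {
  sched <- canonical_schedule()
  spec <- model_spec("M2")
  # beta = 0: uniform choices, likelihood T log 2
  p0 <- agent_params(beta = 0, play_bias = 1, kappa_intercept = 0,
                     eta = 0.2, spec = spec)
  expect_equal(negative_log_posterior(p0, spec, sched |>
                 dplyr::mutate(action = "play"), log_prior = NULL),
               714 * log(2))
  # near-greedy agent on a certain-reward stimulus plays almost always
  certain <- build_schedule(task_config(n_stimuli = 1,
                                        blocks_per_stimulus = 1,
                                        block_length_range = c(200, 200),
                                        total_trials = 200,
                                        probability_levels = 1, seed = 2))
  pg <- agent_params(beta = 10, play_bias = 0, kappa_intercept = 0,
                     eta = 0, spec = spec)
  sim <- simulate_agent(pg, spec, certain, seed = 4)
  expect_gt(mean(sim$action[101:200] == "play"), 0.95)
})

test_that("parameter constructor validates bounds and completeness", {
  expect_error(agent_params(beta = -1, spec = model_spec("M1")),
               "out of bounds")
  expect_error(agent_params(beta = 1, eta = 1.2, spec = model_spec("M2")),
               "out of bounds")
  expect_error(agent_params(beta = 1, spec = model_spec("M3")), "Missing")
})
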