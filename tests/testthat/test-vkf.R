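test_that("the Kalman update matches its closed form", {
  ks <- kalman_step(m = 0, w = 0.1, o = 1, v = 0.1, s = 0.2)
  expect_equal(ks$alpha, 0.5)
  expect_equal(ks$delta, 1)
  expect_equal(ks$m, 0.5)
  expect_equal(ks$w, 0.1)

  # infinite-noise limit: no learning
  ks2 <- kalman_step(0.3, 0.1, 1, 0.1, 1e9)
  expect_lt(ks2$alpha, 1e-8)
  expect_equal(ks2$m, 0.3, tolerance = 1e-8)

  # zero prediction error leaves the mean, variance still grows/shrinks
  ks3 <- kalman_step(0.4, 0.05, 0.4, 0.1, 0.1)
  expect_equal(ks3$m, 0.4)
  expect_equal(ks3$w, (1 - ks3$alpha) * (0.05 + 0.1))

  expect_error(kalman_step(0, -0.1, 0, 0.1, 0.1), "positive")
})

test_that("particle propagation is a martingale with Beta(eta) noise", {
  set.seed(1)
  lambda <- 0.1
  eta <- 1 - lambda
  eps <- rbeta(1e5, 0.5 * eta / (1 - eta), 0.5)
  expect_equal(mean(eps), eta,
               tolerance = 3 * sd(eps) / sqrt(1e5) / eta + 1e-3)

  z1 <- propagate_particles(rep(1, 1e5), lambda)
  expect_equal(mean(z1), 1, tolerance = 3 * sd(z1) / sqrt(1e5))
  expect_true(all(z1 > 0))

  # slow-update limit concentrates near the current value
  z2 <- propagate_particles(rep(1, 1e4), 1e-4)
  expect_lt(max(abs(z2 - 1)), 0.2)
})

test_that("particle weights follow the Gaussian predictive density", {
  # identical particles stay uniform
  b <- weight_update(rep(0.25, 4), rep(0, 4), rep(0.1, 4), rep(0.1, 4),
                     rep(0.1, 4), o = 0.3)
  expect_equal(b, rep(0.25, 4))

  # hand-computed ratio 0.3 : 0.1 normalizes to 0.75 / 0.25
  var_tot <- 0.3
  m1 <- 0
  dens_target <- c(0.3, 0.1)
  # choose observations whose densities have exactly that ratio
  o <- 0.2
  d1 <- dnorm(o, 0, sqrt(var_tot))
  m2 <- o + sqrt(-2 * var_tot * log(dens_target[2] / dens_target[1] *
                                      d1 * sqrt(2 * pi * var_tot)))
  b2 <- weight_update(c(0.5, 0.5), c(m1, m2), c(0.1, 0.1), c(0.1, 0.1),
                      c(0.1, 0.1), o = o)
  expect_equal(b2, c(0.75, 0.25), tolerance = 1e-10)

  # dominance: the particle predicting the outcome takes almost all mass
  b3 <- weight_update(c(0.5, 0.5), c(0.5, 50), c(0.01, 0.01),
                      c(0.01, 0.01), c(0.01, 0.01), o = 0.5)
  expect_gt(b3[1], 0.999)
})

test_that("effective sample size gates systematic resampling strictly", {
  expect_equal(effective_sample_size(rep(0.25, 4)), 4)
  expect_equal(effective_sample_size(c(1, 0, 0, 0)), 1)

  set.seed(2)
  # uniform weights: never resampled
  expect_null(systematic_resample(rep(0.25, 4)))
  # ESS ratio exactly at the threshold: strict inequality, no resample
  expect_null(systematic_resample(c(0.5, 0.5, 0, 0), threshold = 0.5))
  # degenerate weights: every copy comes from the surviving particle
  idx <- systematic_resample(c(0, 1, 0, 0), threshold = 0.5)
  expect_equal(idx, rep(2L, 4))
})

test_that("the filter converges on stationary outcomes", {
  set.seed(3)
  run <- run_vkf(rnorm(150, 0.8, 0.05),
                 vkf_config(n_particles = 300), seed = 4)
  expect_equal(mean(run$m[101:150]), 0.8, tolerance = 0.05)
  expect_lt(mean(run$alpha[101:150]), mean(run$alpha[1:20]))
  run2 <- run_vkf(rnorm(150, 0.8, 0.05),
                  vkf_config(n_particles = 300), seed = 4)
  expect_false(identical(run$m, run2$m))  # outcomes differ (global RNG)
  o <- rnorm(50, 0.5, 0.1)
  expect_identical(run_vkf(o, vkf_config(n_particles = 100), seed = 5)$m,
                   run_vkf(o, vkf_config(n_particles = 100), seed = 5)$m)
})

test_that("frozen dynamics reach the Kalman steady-state learning rate", {
  # with lambda -> 0, v and s stay at v0, s0; the stationary gain solves
  # alpha = (w* + v) / (w* + v + s), w* = (1 - alpha)(w* + v)
  v <- 0.1; s <- 0.1
  u <- (v + sqrt(v^2 + 4 * v * s)) / 2
  alpha_star <- u / (u + s)
  expect_equal(alpha_star, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  set.seed(6)
  run <- run_vkf(rnorm(250, 0.5, sqrt(s)),
                 vkf_config(lambda_v = 1e-5, lambda_s = 1e-5, v0 = v,
                            s0 = s, n_particles = 200), seed = 7)
  expect_equal(mean(run$alpha[151:250]), alpha_star, tolerance = 0.02)
})

test_that("the stochasticity lesion clamps s and inflates volatility", {
  sched <- canonical_schedule()
  les <- vkf_task_sim(sched, vkf_config(n_particles = 400,
                                        lesioned = TRUE), seed = 8)
  expect_equal(les$stochasticity, rep(0.001, nrow(les)),
               tolerance = 1e-12)
  ctl <- vkf_task_sim(sched, vkf_config(n_particles = 400), seed = 8)
  expect_gt(mean(les$volatility), mean(ctl$volatility))
  # control's stochasticity estimate separates the coarse outcome-noise
  # regimes (random 0.05 vs low 0.01; the 0.02/0.01 contrast is below
  # the filter's resolution at task length)
  by_noise <- tapply(ctl$stochasticity, ctl$noise_level, mean)
  expect_gt(by_noise["random"], by_noise["low"])
})

test_that("more particles means less Monte-Carlo variance", {
  set.seed(9)
  o <- rnorm(60, 0.6, 0.1)
  traj_var <- function(n_particles) {
    ms <- vapply(1:12, function(i)
      run_vkf(o, vkf_config(n_particles = n_particles),
              seed = 50 + i)$m[60], numeric(1))
    var(ms)
  }
  expect_lt(traj_var(400), traj_var(25))
})

test_that("choice simulation is centered and seeded", {
  ch <- vkf_choice_sim(rep(0.5, 100), decision_noise = 3, seed = 1)
  expect_true(all(ch$p_play == 0.5))
  ch0 <- vkf_choice_sim(runif(100), decision_noise = 0, seed = 1)
  expect_true(all(ch0$p_play == 0.5))
  a <- vkf_choice_sim(runif(50, 0.3, 0.9), seed = 2)
  b <- vkf_choice_sim(a$p_play * 0 + qlogis(a$p_play) / 6 + 0.5, seed = 2)
  expect_equal(a$action, b$action)

  sim <- vkf_task_sim(canonical_schedule(),
                      vkf_config(n_particles = 100), seed = 3)
  expect_identical(sim$action,
                   vkf_task_sim(canonical_schedule(),
                                vkf_config(n_particles = 100),
                                seed = 3)$action)
  # weights invariants surfaced in the trajectory
  expect_true(all(sim$p_play >= 0 & sim$p_play <= 1))
  expect_true(all(sim$volatility > 0))
})
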