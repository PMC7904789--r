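test_that("noiseless perfect integration reproduces the exact ramp", {
  cfg <- integrator_config(tau = 0.2, sigma_i = 0, sigma_s = 0,
                           duration_s = 2, seed = 1)
  ens <- simulate_trials(potential_spec("flat", mu = 0.3), cfg, n_trials = 5)
  expect_equal(ens$x_final, rep(0.3 * 2 / 0.2, 5), tolerance = 1e-12)
  expect_true(all(ens$choices == 1))
})

test_that("the noiseless double-well always reaches the correct attractor", {
  cfg <- integrator_config(sigma_i = 0, sigma_s = 0, duration_s = 2, seed = 2)
  ens <- simulate_trials(potential_spec("double_well", mu = 0.15, alpha = 1),
                         cfg, n_trials = 10)
  expect_true(all(ens$choices == 1))
  expect_true(all(ens$first_visit == 1))
  expect_true(all(ens$n_transitions == 0))
})

test_that("negating the stimulus flips every deterministic choice", {
  cfg <- integrator_config(sigma_i = 0, duration_s = 2, seed = 3)
  st <- gaussian_frames(300, 400, mu = 0.1, sigma_s = 0.5, seed = 4,
                        frame_duration = cfg$dt)
  pot <- potential_spec("double_well", mu = 0, alpha = 1)
  r1 <- simulate_trials(pot, cfg, stimuli = st)
  st_neg <- st
  st_neg$frames <- -st$frames
  st_neg$mu_per_trial <- -st$mu_per_trial
  r2 <- simulate_trials(pot, cfg, stimuli = st_neg)
  expect_identical(r2$choices, -r1$choices)
})

test_that("absorbing bounds freeze the trajectory at +/- B", {
  cfg <- integrator_config(sigma_i = 0.6, duration_s = 2, seed = 5)
  ens <- simulate_trials(potential_spec("linear", mu = 0), cfg,
                         bounds = bound_spec("absorbing", 1), n_trials = 2000,
                         record_trajectories = TRUE)
  hit <- abs(ens$x_final) >= 1 - 1e-12
  expect_true(any(hit))
  expect_true(all(abs(ens$x_final[hit]) == 1))
  expect_true(all(abs(ens$x_final[!hit]) < 1))
  # once absorbed the trajectory never moves again
  tr <- ens$trajectories[, which(hit)[1]]
  k <- which(abs(tr) >= 1)[1]
  expect_true(all(tr[k:length(tr)] == tr[k]))
})

test_that("absorption probability agrees with a fine-step oracle", {
  p_abs <- function(dt_div, n, seed) {
    cfg <- integrator_config(dt = 0.2 / dt_div, sigma_i = 0.6, duration_s = 2,
                             seed = seed)
    ens <- simulate_trials(potential_spec("linear", mu = 0), cfg,
                           bounds = bound_spec("absorbing", 1), n_trials = n)
    mean(abs(ens$x_final) >= 1 - 1e-12)
  }
  n <- 4000
  coarse <- p_abs(40, n, 6)
  fine <- p_abs(400, n, 7)
  se <- sqrt(coarse * (1 - coarse) / n + fine * (1 - fine) / n)
  expect_lt(abs(coarse - fine), 2 * se + 0.02)  # 0.02 allows the O(sqrt(dt))
                                                # Euler boundary-layer bias
})

test_that("halving the step leaves cell accuracies unchanged within noise", {
  acc <- function(div, seed) {
    cfg <- integrator_config(dt = 0.2 / div, sigma_i = 0, duration_s = 2,
                             seed = seed)
    ens <- simulate_trials(potential_spec("double_well", mu = 0.15, alpha = 1),
                           cfg, n_trials = 4000)
    mean(ens$choices == 1)
  }
  a40 <- acc(40, 8)
  a80 <- acc(80, 9)
  se <- sqrt(2 * 0.25 / 4000)
  expect_lt(abs(a40 - a80), 2 * se)
})

test_that("empirical first-visit frequency matches the closed form", {
  pot <- potential_spec("double_well", mu = 0.15, alpha = 1)
  cfg <- integrator_config(sigma_i = 0, sigma_s = 0.4, duration_s = 1, seed = 10)
  ens <- simulate_trials(pot, cfg, n_trials = 20000)
  p_emp <- mean(ens$first_visit == 1, na.rm = TRUE)
  p_th <- first_visit_probability(pot, 0.4, method = "quadrature")
  expect_lt(abs(p_emp - p_th), 2 * sqrt(p_th * (1 - p_th) / 20000) + 0.01)
})

test_that("ambiguous stimuli give chance accuracy and +/-1 choices", {
  ps <- run_psychometric(potential_spec("double_well", mu = 0, alpha = 1),
                         mu_grid = 0, sigma_s_grid = 0.5, T_grid = 2,
                         n_trials = 2000, config = integrator_config(sigma_i = 0.1),
                         seed = 11)
  expect_lt(abs(ps$accuracy - 0.5), 3 * ps$se)
  expect_error(run_psychometric(potential_spec("flat"), mu_grid = 0,
                                sigma_s_grid = 1, n_trials = 10), ">= 100")
})

test_that("transition bookkeeping uses full hysteresis", {
  # strong fluctuations: switches occur; transition times alternate in sign
  cfg <- integrator_config(sigma_i = 0, sigma_s = 0.9, duration_s = 4, seed = 12)
  ens <- simulate_trials(potential_spec("double_well", mu = 0, alpha = 1), cfg,
                         n_trials = 200, record_transition_times = TRUE)
  expect_gt(mean(ens$n_transitions), 0.2)
  has <- which(ens$n_transitions >= 2)
  expect_true(length(has) > 0)
  for (i in has[seq_len(min(10, length(has)))]) {
    expect_true(all(diff(sign(ens$transition_times[[i]])) != 0))
  }
})
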