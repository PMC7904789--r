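test_that("consistency is exactly 1 without internal noise", {
  pot <- potential_spec("double_well", mu = 0, alpha = 1)
  cfg <- integrator_config(sigma_i = 0, duration_s = 1)
  cr <- double_pass(pot, cfg, sigma_s_grid = c(0.3, 0.6), n_stimuli = 30,
                    n_passes = 5, seed = 1)
  expect_equal(unname(cr$consistency), c(1, 1))
})

test_that("consistency is at chance when internal noise dominates", {
  pot <- potential_spec("double_well", mu = 0, alpha = 1)
  cfg <- integrator_config(sigma_i = 0.3, duration_s = 1)
  cr <- double_pass(pot, cfg, sigma_s_grid = 0.01, n_stimuli = 150,
                    n_passes = 10, seed = 2)
  expect_lt(abs(cr$consistency - 0.5), 3 * cr$se + 0.02)
})

test_that("perfect integration of zero-integral stimuli is at chance", {
  cfg <- integrator_config(sigma_i = 0.1, duration_s = 1)
  cr <- double_pass(potential_spec("flat"), cfg, sigma_s_grid = c(0.3, 0.8),
                    n_stimuli = 100, n_passes = 10, seed = 3)
  expect_true(all(abs(cr$consistency - 0.5) < 3 * cr$se + 0.02))
})

test_that("the pass-pair estimator is unbiased on Bernoulli data", {
  # closed form: consistency = p^2 + (1-p)^2
  set.seed(4)
  p <- 0.3; n_passes <- 5; n_stim <- 4000
  m <- rbinom(n_stim, n_passes, p)
  est <- (choose(m, 2) + choose(n_passes - m, 2)) / choose(n_passes, 2)
  truth <- p^2 + (1 - p)^2
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(n_stim))
})

test_that("the transition diagnostic vanishes without internal noise", {
  pot <- potential_spec("double_well", mu = 0, alpha = 1)
  cfg <- integrator_config(sigma_i = 0, duration_s = 1)
  dg <- transition_diag(pot, cfg, sigma_s_grid = c(0.3, 0.6), sigma_i = 0,
                        n_trials = 100, seed = 5)
  expect_equal(dg$delta, c(0, 0))
  expect_error(transition_diag(potential_spec("flat"), cfg, 0.3, 0.1, 100, 6),
               "double-well")
})
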