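test_that("gaussian frames have the stated moments", {
  st <- gaussian_frames(1000, 20, mu = 0, sigma_s = 1, seed = 1)
  se_grand <- 1 / sqrt(1000 * 20)
  expect_lt(abs(mean(st$frames)), 3 * se_grand)
  expect_lt(abs(sd(as.vector(st$frames)) - 1), 3 * se_grand)

  # degenerate noise: every frame equals the mean exactly
  st0 <- gaussian_frames(50, 7, mu = 0.5, sigma_s = 0, seed = 2)
  expect_true(all(st0$frames == 0.5))

  # trial sums ~ Normal(n_frames * mu, n_frames * sigma^2)
  st2 <- gaussian_frames(5000, 10, mu = 0.15, sigma_s = 0.58, seed = 3)
  sums <- rowSums(st2$frames)
  expect_lt(abs(mean(sums) - 1.5), 3 * sqrt(10 * 0.58^2 / 5000))
  expect_lt(abs(var(sums) / (10 * 0.58^2) - 1), 3 * sqrt(2 / 4999))
})

test_that("zero-integral stimuli are exactly centered and scaled", {
  st <- zero_integral_frames(200, 40, sigma_s = 0.3, seed = 4)
  expect_equal(unname(rowSums(st$frames)), rep(0, 200), tolerance = 1e-12)
  pop_sd <- sqrt(rowMeans((st$frames - rowMeans(st$frames))^2))
  expect_equal(unname(pop_sd), rep(0.3, 200), tolerance = 1e-12)

  # two frames are forced to (+s, -s) in some order
  st2 <- zero_integral_frames(20, 2, sigma_s = 1, seed = 5)
  expect_true(all(abs(abs(st2$frames) - 1) < 1e-12))

  # pooled frame distribution approximately Normal(0, sigma^2)
  st3 <- zero_integral_frames(500, 40, sigma_s = 0.3, seed = 6)
  ks <- suppressWarnings(ks.test(as.vector(st3$frames), "pnorm", 0, 0.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("brightness pulses are exactly compensated across segments", {
  # no pulses: trial mean equals the generative gap in every trial
  st <- brightness_disc_frames(200, 2, gen_mean_gap = 0.05, frame_sd = 0,
                               pulse_prob = 0, seed = 7)
  expect_equal(unname(rowMeans(st$frames)), unname(st$mu_per_trial))

  # with pulses (noise off): the five segment means still sum to 5 * gap
  st2 <- brightness_disc_frames(500, 2, gen_mean_gap = 0.05, frame_sd = 0,
                                pulse_prob = 1, pulse_size = 0.2, seed = 8)
  seg <- sapply(1:5, function(s) rowMeans(st2$frames[, (s - 1) * 4 + 1:4]))
  expect_equal(unname(rowSums(seg)), unname(5 * st2$mu_per_trial), tolerance = 1e-12)
  # compensation makes segment-mean deviations anticorrelated
  dev <- seg - st2$mu_per_trial
  r1 <- cor(as.vector(dev[, 1:4]), as.vector(dev[, 2:5]))
  expect_lt(r1, 0)

  expect_error(brightness_disc_frames(10, 2, pulse_prob = 1.5), "pulse_prob")
  expect_error(brightness_disc_frames(10, 1.7), "five equal segments")
})

test_that("the two-pulse design enumerates the published conditions", {
  d <- two_pulse_design()
  expect_equal(sum(is.na(d$coh2)), 6)                       # single-pulse levels
  dbl <- d[!is.na(d$coh2), ]
  expect_equal(nrow(unique(dbl[, c("coh1", "coh2")])), 9)   # coherence sequences
  expect_equal(sort(unique(dbl$delay_ms)), c(0, 120, 360, 1080))
  expect_equal(nrow(two_pulse_design(coherences = 6.4, delays_ms = 120)) - 6, 1)
  expect_error(two_pulse_design(coherences = -1), "non-negative")
})

test_that("OU stimulus currents have the right mean, sd and timescale", {
  st0 <- ou_currents(0.1, sigma_s = 0, duration_s = 0.5, I0 = 50, seed = 9)
  expect_equal(unname(range(st0$I_A)), rep(50 * 1.1, 2))
  expect_equal(unname(range(st0$I_B)), rep(50 * 0.9, 2))

  st <- ou_currents(0, sigma_s = 5, duration_s = 60, dt_ms = 1, I0 = 50, seed = 10)
  n <- length(st$I_A)
  expect_lt(abs(mean(st$I_A) - mean(st$I_B)), 6 * 5 / sqrt(n / 40))
  # autocorrelation time from exponential decay of the sample ACF
  ac <- acf(st$I_A, lag.max = 15, plot = FALSE)$acf[-1]
  fit <- lm(log(ac) ~ seq_along(ac))
  tau_hat <- -1 / coef(fit)[2]          # in ms (dt = 1 ms)
  expect_lt(abs(tau_hat - 20) / 20, 0.1)
})

test_that("stimulus generation is reproducible and lives in its own stream", {
  a <- gaussian_frames(50, 30, 0.1, 0.5, seed = 11)
  b <- gaussian_frames(50, 30, 0.1, 0.5, seed = 11)
  expect_identical(a, b)
  z1 <- zero_integral_frames(10, 10, 1, seed = 12)
  z2 <- zero_integral_frames(10, 10, 1, seed = 12)
  expect_identical(z1, z2)

  # regenerating stimuli between runs must not perturb the internal draws
  pot <- potential_spec("double_well", mu = 0, alpha = 1)
  cfg <- integrator_config(sigma_i = 0.3, seed = 13)
  st <- gaussian_frames(100, 400, 0, 0.4, seed = 14, frame_duration = cfg$dt)
  r1 <- simulate_trials(pot, cfg, stimuli = st)
  invisible(gaussian_frames(100, 400, 0, 0.4, seed = 999, frame_duration = cfg$dt))
  r2 <- simulate_trials(pot, cfg, stimuli = st)
  expect_identical(r1$choices, r2$choices)
})

test_that("stimulus ensembles round-trip through CSV + JSON", {
  st <- zero_integral_frames(12, 8, 0.7, seed = 15, frame_duration = 0.01)
  path <- file.path(tempdir(), "stim.csv")
  write_stimuli(st, path)
  back <- read_stimuli(path)
  expect_equal(back$frames, st$frames, tolerance = 1e-12)
  expect_equal(back$kind, st$kind)
  expect_equal(back$sigma_s, st$sigma_s)
  expect_equal(back$frame_duration, st$frame_duration)
})
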