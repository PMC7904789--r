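truth <- c(k = 0.012, alpha = 0.70, sigma = 0.52, tau = 3.3)

test_that("pulse accuracy predictions have the right structure", {
  expect_equal(predict_pulse_accuracy(truth, 0), 0.5)
  expect_equal(predict_pulse_accuracy(truth, 0, 0), 0.5)
  # strong pulse, weak noise: near-certain
  strong <- c(k = 0.012, alpha = 0.70, sigma = 0.08, tau = 3.3)
  expect_gt(predict_pulse_accuracy(strong, 51.2), 0.999)
  # a second congruent pulse of the same strength never hurts
  cc <- c(3.2, 6.4, 12.8)
  p2cc <- predict_pulse_accuracy(truth, cc, cc)
  p1cc <- predict_pulse_accuracy(truth, cc)
  expect_true(all(p2cc >= p1cc))
  # under the two-state chain the first pulse anchors the state, so the
  # stronger-first ordering scores higher (see the methods discussion of the
  # pulse-order asymmetry)
  p_up <- predict_pulse_accuracy(truth, 3.2, 12.8)
  p_dn <- predict_pulse_accuracy(truth, 12.8, 3.2)
  expect_gte(p_dn, p_up)
  d <- two_pulse_design()
  dbl <- d[!is.na(d$coh2), c("coh1", "coh2")]
  p2 <- predict_pulse_accuracy(truth, dbl$coh1, dbl$coh2)
  expect_true(all(p2 > 0 & p2 < 1))
})

test_that("maximum likelihood refits recover the identifiable structure", {
  tab <- simulate_condition_table(truth,
                                  design = two_pulse_design(n_per_condition = 3000),
                                  seed = 10)
  fit <- dwm_fit(tab, n_restarts = 5, maxit = 800, seed = 11)
  est <- coef(fit)
  # the four raw parameters are covered by their own intervals
  ci <- fit$ci95
  expect_true(all(truth >= ci[, "lower"] & truth <= ci[, "upper"]))
  # the identifiable combinations are pinned tightly despite the scaling ridge
  expect_equal(unname(est["alpha"]^2 / est["sigma"]^2),
               unname(truth["alpha"]^2 / truth["sigma"]^2), tolerance = 0.1)
  expect_equal(unname(est["k"] / est["alpha"]^1.5),
               unname(truth["k"] / truth["alpha"]^1.5), tolerance = 0.1)
  # fitted predictions track the observed frequencies
  expect_lt(max(abs(fit$table$predicted - fit$table$observed)), 0.05)
  expect_s3_class(fit, "dwm_fit")
  expect_equal(length(residuals(fit)), nrow(fit$table))
  expect_equal(dim(vcov(fit)), c(4L, 4L))
  expect_equal(unname(predict(fit, data.frame(coh1 = 0, coh2 = NA))), 0.5)
})

test_that("a table at chance drags the drift scaling to its floor", {
  d <- two_pulse_design(n_per_condition = 2000)
  set.seed(12)
  tab <- data.frame(coh1 = d$coh1, coh2 = d$coh2, n_trials = d$n,
                    n_correct = rbinom(nrow(d), d$n, 0.5))
  fit <- dwm_fit(tab, n_restarts = 4, maxit = 600, seed = 13)
  P <- predict(fit)
  expect_true(all(abs(P - 0.5) < 0.03))
})

test_that("the likelihood at the truth dominates a perturbed barrier", {
  ll <- function(p, tab) {
    P <- predict_pulse_accuracy(p, tab$coh1, tab$coh2)
    sum(tab$n_correct * log(P) + (tab$n_trials - tab$n_correct) * log1p(-P))
  }
  pert <- truth; pert["alpha"] <- 2 * truth["alpha"]
  wins <- 0
  for (r in 1:20) {
    tab <- simulate_condition_table(truth,
                                    design = two_pulse_design(n_per_condition = 2000),
                                    seed = 100 + r)
    wins <- wins + (ll(truth, tab) >= ll(pert, tab))
  }
  expect_gte(wins, 18)
})

test_that("the primacy-recency index reads off the pulse weights", {
  set.seed(14)
  d <- expand.grid(coh1 = c(3.2, 6.4, 12.8), coh2 = c(3.2, 6.4, 12.8))
  idx <- rep(seq_len(nrow(d)), each = 700)
  # equal weights: PRI ~ 0
  p_eq <- plogis(-0.3 + 0.08 * (d$coh1[idx] + d$coh2[idx]))
  tr_eq <- data.frame(coh1 = d$coh1[idx], coh2 = d$coh2[idx],
                      correct = rbinom(length(idx), 1, p_eq))
  expect_lt(abs(pri(tr_eq)$pri), 0.15)
  # only the second pulse matters: PRI -> 1
  p_2 <- plogis(-0.3 + 0.16 * d$coh2[idx])
  tr_2 <- data.frame(coh1 = d$coh1[idx], coh2 = d$coh2[idx],
                     correct = rbinom(length(idx), 1, p_2))
  expect_gt(pri(tr_2)$pri, 0.7)
  # model-simulated trials at the fitted parameters weight the anchoring
  # first pulse more (the two-state chain is primacy-dominated)
  tr_m <- simulate_pulse_trials(truth, seed = 15)
  pm <- pri(tr_m)
  expect_gt(pm$beta1, pm$beta2)
  expect_true(pm$pri >= -1 && pm$pri <= 1)
  expect_error(pri(data.frame(coh1 = 1, coh2 = 1, correct = 1)), "vary")
})

test_that("delay robustness separates the attractor model from the integrator", {
  dr <- delay_robustness(truth)
  expect_equal(round(dr$sigma_i_max, 2), 0.32)
  # attractor accuracy moves < 1% across delays up to ~1 s at sigma_I^max
  expect_lt(max(dr$curves$dwm) - min(dr$curves$dwm), 0.01)
  # the perfect integrator decays strictly with delay
  expect_true(all(diff(dr$curves$pi) < 0))
  # the bound grows with barrier and with a slower clock
  b1 <- delay_noise_bound(0.5, 3.3, 1.08)
  b2 <- delay_noise_bound(0.9, 3.3, 1.08)
  b3 <- delay_noise_bound(0.7, 1.5, 1.08)
  b4 <- delay_noise_bound(0.7, 6.0, 1.08)
  expect_lt(b1, b2)
  expect_lt(b3, b4)
})
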