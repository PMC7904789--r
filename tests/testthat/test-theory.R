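test_that("symmetric escape rate matches the hand-evaluated Kramers formula", {
  # prefactor sqrt(2.8 * 1.4)/(2 pi), barrier alpha^2/4 = 0.1225
  r <- transition_rates(potential_spec("double_well", 0, alpha = 0.70), 0.32)
  hand <- sqrt(2.8 * 1.4) / (2 * pi) * exp(-2 * 0.1225 / 0.32^2)
  expect_equal(r[["k_C"]], hand, tolerance = 1e-10)
  expect_equal(r[["k_C"]], 0.0288, tolerance = 1e-2)
  expect_equal(r[["k_C"]], r[["k_E"]])
})

test_that("the rate ratio grows exponentially with the tilt", {
  # the expansion parameter is mu/alpha^(3/2); use a high barrier
  a <- 2; s <- 0.6
  for (mu in c(0.01, 0.03, 0.05)) {
    r <- transition_rates(potential_spec("double_well", mu, alpha = a), s)
    expect_equal(r[["k_C"]] / r[["k_E"]], exp(4 * mu * sqrt(a / 2) / s^2),
                 tolerance = 0.05)
  }
})

test_that("trial transition probabilities have the right limits", {
  r <- transition_rates(potential_spec("double_well", 0.1, alpha = 1), 0.45)
  t0 <- trial_transition_probs(r, 0)
  expect_equal(unname(t0[c("p_C", "p_E")]), c(0, 0))
  tinf <- trial_transition_probs(r, 1e6)
  expect_equal(tinf[["p_C"]], tinf[["p_inf"]])
  expect_equal(tinf[["p_E"]], 1 - tinf[["p_inf"]])
  tmid <- trial_transition_probs(r, 5)
  expect_gt(tmid[["p_C"]], tmid[["p_E"]])  # correcting beats error for mu > 0
})

test_that("the two algebraic forms of the accuracy agree everywhere", {
  for (mu in c(0, 0.05, 0.15, 0.3)) for (s in c(0.2, 0.4, 0.7)) for (Tt in c(0.5, 2.5, 10)) {
    kp <- kramers_accuracy(potential_spec("double_well", mu, alpha = 1), s, Tt)
    # the constructor itself asserts the 1e-12 agreement; check bounds here
    expect_true(kp$accuracy >= min(kp$p0, kp$p_inf) - 1e-12)
    expect_true(kp$accuracy <= max(kp$p0, kp$p_inf) + 1e-12)
    if (mu == 0) expect_equal(kp$accuracy, 0.5)
  }
})

test_that("first-visit probability: symmetry, determinism limit, quadrature", {
  pot0 <- potential_spec("double_well", 0, alpha = 1)
  expect_equal(first_visit_probability(pot0, 0.5), 0.5)
  pot <- potential_spec("double_well", 0.15, alpha = 1)
  expect_gt(first_visit_probability(pot, 0.01), 0.999999)
  # erf closed form tracks the exact quadrature in its regime of validity
  # the quartic-free closed form deviates from the exact splitting integral
  # by a few percent at these noise levels
  for (s in c(0.2, 0.3, 0.4)) {
    expect_equal(first_visit_probability(pot, s),
                 first_visit_probability(pot, s, method = "quadrature"),
                 tolerance = 0.06)
  }
})

test_that("delay switch probability reproduces the fitted-parameter chain", {
  expect_equal(delay_switch_probability(0.70, 0.32, 3.3, 1.08), 0.0093,
               tolerance = 0.01)
  expect_equal(delay_switch_probability(0.70, 0, 3.3, 1.08), 0)
  b <- delay_noise_bound(0.70, 3.3, 1.08, threshold = 0.01)
  expect_equal(round(b, 2), 0.32)
  expect_error(delay_noise_bound(0.7, 3.3, 1.08, threshold = 2), "threshold")
})

test_that("the interior accuracy maximum exists below the critical tilt only", {
  pk_lo <- accuracy_peak(potential_spec("double_well", 0.15, alpha = 1), 10,
                         sigma_range = c(0.1, 1.1))
  expect_false(is.na(pk_lo$sigma_star))
  expect_gt(pk_lo$sigma_star, 0.15)
  # well above mu_C = 0.354 the curve is monotone
  pk_hi <- accuracy_peak(potential_spec("double_well", 0.5, alpha = 1), 10,
                         sigma_range = c(0.1, 1.1))
  expect_true(is.na(pk_hi$sigma_star))
})
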