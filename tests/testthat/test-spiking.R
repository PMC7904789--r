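test_that("connectivity is seeded and respects the wiring plan", {
  p <- network_params()
  n1 <- build_network(p, seed = 1)
  n2 <- build_network(p, seed = 1)
  expect_identical(n1$adj_idx, n2$adj_idx)
  expect_identical(n1$adj_ptr, n2$adj_ptr)
  n3 <- build_network(p, seed = 2)
  expect_false(identical(n1$adj_idx, n3$adj_idx))
  # connection count ~ eps * (possible pairs), no A<->B excitation
  n_e <- p$n_e; n_i <- p$n_i
  expected <- 0.1 * (2 * n_e * (n_e - 1) + 2 * n_e * n_i + 2 * n_i * n_e)
  expect_lt(abs(length(n1$adj_idx) - expected) / expected, 0.05)
  # no recurrent synapses at all when eps = 0
  n0 <- build_network(network_params(eps = 0), seed = 1)
  expect_equal(length(n0$adj_idx), 0)
})

test_that("the tuned operating point is bistable", {
  expect_true(check_attractor_persistence(network_params(), seed = 3))
})

test_that("baseline-driven activity is stationary before a decision forms", {
  # the stimulus-free network is nearly silent by construction; stationarity
  # is meaningful at the baseline-current-driven symmetric state
  net <- build_network(network_params(), seed = 4)
  trl <- run_trial(net, NULL, duration_s = 1.0, seed = 5)
  # drop the pre-stimulus interval and the onset transient
  bins <- (floor(0.7 / (trl$bin_ms / 1000)) + 1):floor(1.5 / (trl$bin_ms / 1000))
  cnt <- (trl$rate_A + trl$rate_B)[bins]
  half <- length(cnt) %/% 2
  h1 <- mean(cnt[seq_len(half)])
  h2 <- mean(cnt[(half + 1):(2 * half)])
  pooled_se <- sd(cnt) * sqrt(2 / half)
  expect_lt(abs(h1 - h2), max(0.1 * mean(cnt), 3 * pooled_se) + 1e-9)
})

test_that("ambiguous stimuli split choices; the winner has the higher late rate", {
  p <- network_params()
  ch <- numeric(40)
  for (i in 1:40) {
    net <- build_network(p, seed = 100 + i)
    st <- ou_currents(0, 10, duration_s = 1, I0 = p$I0_pA, seed = 200 + i)
    trl <- run_trial(net, st, duration_s = 1, seed = 300 + i)
    ch[i] <- trl$choice
    if (i == 1) {
      late_w <- if (trl$choice == 1) tail(trl$rate_A, 3) else tail(trl$rate_B, 3)
      late_l <- if (trl$choice == 1) tail(trl$rate_B, 3) else tail(trl$rate_A, 3)
      expect_gte(mean(late_w), mean(late_l))
    }
  }
  p_right <- mean(ch == 1)
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / 40))
})

test_that("the experiment driver returns a tidy surface with kernels", {
  ex <- run_spiking_experiment(network_params(), mu = 0.2,
                               sigma_s_grid_pA = 8, T_grid_s = 1,
                               n_trials = 50, seed = 6)
  expect_equal(nrow(ex$cells), 1)
  expect_true(ex$cells$accuracy >= 0 && ex$cells$accuracy <= 1)
  expect_gt(ex$cells$accuracy, 0.7)   # strong tilt, weak fluctuations
  k <- ex$kernels[[1]]
  if (!is.null(k)) {
    expect_equal(length(k$pk), 10)
    expect_true(all(k$pk >= 0 & k$pk <= 1))
  }
})
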