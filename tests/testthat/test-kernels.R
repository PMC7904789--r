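test_that("rank-based AUROC equals the all-pairs oracle, ties included", {
  set.seed(1)
  for (i in 1:20) {
    x <- round(rnorm(13), 1)   # rounding forces ties
    y <- round(rnorm(9), 1)
    expect_equal(dwell:::auroc(x, y), auroc_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("kernels detect exactly which frames drive the choice", {
  st <- gaussian_frames(400, 10, mu = 0, sigma_s = 1, seed = 2,
                        frame_duration = 0.1)
  # choices independent of the stimulus: flat kernel at 0.5
  ch_rand <- with(list(), {set.seed(3); sample(c(-1, 1), 400, TRUE)})
  pk0 <- compute_pk(st, ch_rand)
  expect_true(all(abs(pk0$pk - 0.5) < 3 * 0.5 / sqrt(100)))

  # choices = sign of frame 1: that frame separates perfectly
  ch1 <- sign(st$frames[, 1])
  pk1 <- compute_pk(st, ch1)
  expect_equal(pk1$pk[1], 1.0)
  expect_true(all(abs(pk1$pk[-1] - 0.5) < 0.1))

  # ideal observer on zero-mean stimuli: flat kernel, slope ~ 0
  ch_int <- sign(rowSums(st$frames))
  pk2 <- compute_pk(st, ch_int)
  expect_lt(abs(as.numeric(pk_slope(pk2))), 0.1)

  expect_error(compute_pk(st, rep(1, 400)), "each choice")
})

test_that("kernel area normalization behaves like a fraction of ideal", {
  st <- gaussian_frames(800, 20, mu = 0, sigma_s = 1, seed = 4,
                        frame_duration = 0.1)
  ideal <- compute_pk(st, sign(rowSums(st$frames)))
  expect_equal(npka(ideal, ideal), 1.0)
  set.seed(5)
  noise <- compute_pk(st, sample(c(-1, 1), 800, TRUE))
  expect_lt(abs(npka(noise, ideal)), 0.15)
  flat <- ideal; flat$pk <- rep(0.5, 20)
  expect_error(npka(ideal, flat), "positive")
})

test_that("the normalized slope is 0 for flat, antisymmetric in time", {
  k <- structure(list(pk = rep(0.7, 10), times = (1:10 - 0.5) * 0.1,
                      bin_s = 0.1, n_trials = 100), class = "pk_kernel")
  expect_equal(as.numeric(pk_slope(k)), 0)
  k2 <- k; k2$pk <- seq(0.5, 0.9, length.out = 10)
  k3 <- k2; k3$pk <- rev(k2$pk)
  expect_equal(as.numeric(pk_slope(k2)), -as.numeric(pk_slope(k3)),
               tolerance = 1e-12)
  expect_gt(as.numeric(pk_slope(k2)), 0)
  k4 <- k; k4$pk <- rep(0.5, 10)
  expect_error(pk_slope(k4), "slope undefined")
})

test_that("bootstrap bands are reproducible and scale with trial count", {
  mk <- function(n, seed) {
    st <- gaussian_frames(n, 10, mu = 0, sigma_s = 1, seed = seed,
                          frame_duration = 0.1)
    list(st = st, ch = sign(rowSums(st$frames)))
  }
  d <- mk(300, 6)
  b1 <- bootstrap_pk(d$st, d$ch, n_boot = 200, seed = 7)
  b2 <- bootstrap_pk(d$st, d$ch, n_boot = 200, seed = 7)
  expect_identical(b1$sem, b2$sem)
  d4 <- mk(1200, 8)
  b4 <- bootstrap_pk(d4$st, d4$ch, n_boot = 200, seed = 9)
  ratio <- median(b1$sem) / median(b4$sem)
  expect_gt(ratio, 1.5)          # ~ 2 expected from sqrt(4)
  expect_lt(ratio, 2.7)
  expect_error(bootstrap_pk(d$st, d$ch, n_boot = 1), ">= 100")
})

test_that("binning to coarser frames preserves the kernel time base", {
  st <- gaussian_frames(200, 40, mu = 0, sigma_s = 1, seed = 10,
                        frame_duration = 0.005)
  pk <- compute_pk(st, sign(rowSums(st$frames)), bin_s = 0.02)
  expect_equal(length(pk$pk), 10)
  expect_equal(pk$times[1], 0.01)
  expect_error(compute_pk(st, sign(rowSums(st$frames)), bin_s = 0.007),
               "multiple")
})
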