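#' Double-pass choice consistency
#'
#' Presents each stimulus realization several times with independent
#' internal-noise draws and estimates the probability that two presentations
#' of the identical stimulus yield the same choice. Only zero-integrated-
#' evidence stimuli are admitted (any nonzero integrated evidence would
#' trivially inflate consistency).
#'
#' Per stimulus, with `n_passes` passes of which `m` ended rightward, the
#' unbiased estimator of `p^2 + (1-p)^2` is the fraction of concordant
#' unordered pass pairs, `(choose(m,2) + choose(n-m,2)) / choose(n,2)` (the
#' U-statistic; the naive plug-in is biased upward by `p(1-p) * 2/n`).
#'
#' @param potential a [potential_spec()] (any family).
#' @param config an [integrator_config()]; its `sigma_i` is the internal noise
#'   and `duration_s`/`dt` set the stimulus grid.
#' @param sigma_s_grid stimulus-fluctuation magnitudes to scan.
#' @param n_stimuli frozen stimulus realizations per grid point.
#' @param n_passes presentations per stimulus (>= 2; default 20, which the
#'   package can afford because it controls the generative process; use 2 for
#'   the strict experimental double-pass protocol).
#' @param bounds a [bound_spec()] (for the canonical models).
#' @param seed master seed; stimuli and internal noise use separate
#'   substreams.
#' @return object of class `consistency_result`: data.frame-like list with
#'   `sigma_s_grid`, `consistency`, `se` (SEM over stimuli), and
#'   `per_stimulus` (matrix n_stimuli x grid).
#' @export
double_pass <- function(potential, config, sigma_s_grid, n_stimuli = 150L,
                        n_passes = 20L, bounds = bound_spec("none"), seed = 1L) {
  if (n_passes < 2) stop("need at least 2 passes per stimulus")
  n_frames <- as.integer(round(config$duration_s / config$dt))
  per_stim <- matrix(NA_real_, n_stimuli, length(sigma_s_grid))
  for (g in seq_along(sigma_s_grid)) {
    st <- zero_integral_frames(n_stimuli, n_frames, sigma_s_grid[g],
                               seed = substream_seed(seed, "stimulus-grid", g),
                               frame_duration = config$dt)
    if (st$kind != "zero_integral") stop("double-pass protocol requires zero-integral stimuli")
    rep_idx <- rep(seq_len(n_stimuli), each = n_passes)
    st_rep <- st
    st_rep$frames <- st$frames[rep_idx, , drop = FALSE]
    st_rep$mu_per_trial <- st$mu_per_trial[rep_idx]
    cfg <- config
    cfg$seed <- substream_seed(seed, "passes", g)
    ens <- simulate_trials(potential, cfg, stimuli = st_rep, bounds = bounds)
    m <- tapply(ens$choices == 1, rep_idx, sum)
    per_stim[, g] <- (choose(m, 2) + choose(n_passes - m, 2)) / choose(n_passes, 2)
  }
  structure(list(sigma_s_grid = sigma_s_grid,
                 consistency = colMeans(per_stim),
                 se = apply(per_stim, 2L, stats::sd) / sqrt(n_stimuli),
                 per_stimulus = per_stim,
                 n_stimuli = n_stimuli, n_passes = n_passes),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  print(data.frame(sigma_s = x$sigma_s_grid, consistency = round(x$consistency, 4),
                   se = round(x$se, 4)))
  invisible(x)
}

#' @export
plot.consistency_result <- function(x, ...) {
  graphics::plot(x$sigma_s_grid, x$consistency, type = "o", pch = 16,
                 xlab = expression(sigma[S]), ylab = "consistency",
                 ylim = c(0.45, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Internal-noise dependence of the attractor-switch probability
#'
#' Diagnostic for the consistency dip: on identical frozen stimuli, the
#' per-trial probability of at least one attractor switch is estimated with
#' internal noise `sigma_i` and with internal noise 0; the returned curve is
#' the absolute difference. It peaks where transitions require internal and
#' stimulus fluctuations to cooperate, which is where consistency dips.
#'
#' @inheritParams double_pass
#' @param sigma_i internal-noise magnitude for the "with" arm.
#' @param n_trials stimuli (= trials) per grid point.
#' @return data.frame with `sigma_s`, `p_with`, `p_without`, `delta`.
#' @export
transition_diag <- function(potential, config, sigma_s_grid, sigma_i,
                            n_trials = 2000L, seed = 1L) {
  if (potential$family != "double_well") stop("transition diagnostic requires the double-well model")
  n_frames <- as.integer(round(config$duration_s / config$dt))
  out <- data.frame(sigma_s = sigma_s_grid, p_with = NA_real_, p_without = NA_real_)
  for (g in seq_along(sigma_s_grid)) {
    st <- zero_integral_frames(n_trials, n_frames, sigma_s_grid[g],
                               seed = substream_seed(seed, "stimulus-grid", g),
                               frame_duration = config$dt)
    cfg <- config
    cfg$seed <- substream_seed(seed, "diag", g)
    cfg$sigma_i <- sigma_i
    with_i <- simulate_trials(potential, cfg, stimuli = st)
    cfg$sigma_i <- 0
    without_i <- simulate_trials(potential, cfg, stimuli = st)
    out$p_with[g] <- mean(with_i$n_transitions >= 1)
    out$p_without[g] <- mean(without_i$n_transitions >= 1)
  }
  out$delta <- abs(out$p_with - out$p_without)
  out
}
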