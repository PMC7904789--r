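#' Frame-based stimulus ensembles
#'
#' A `dwell_stimuli` object holds an ensemble of per-trial evidence traces as
#' a trial-by-frame matrix, together with the frame duration, the per-trial
#' generative mean evidence, the nominal fluctuation magnitude, and a tag
#' identifying the stimulus class. Two couplings into the diffusion engine are
#' used, depending on the class:
#'
#' * `"white"` (kinds `gaussian`, `zero_integral`): frames are sampled on the
#'   integrator step grid; the per-trial mean enters the drift and the
#'   deviations enter like white noise, `sqrt(dt/tau) * (S - mu)`, so that the
#'   integrated fluctuation variance matches a continuous white-noise stimulus
#'   of magnitude `sigma_s`.
#' * `"drift"` (kind `brightness_discs`): frames are slow (100 ms) evidence
#'   values that replace the mean drift itself, `dt/tau * S(t)`, with the
#'   engine's own stimulus noise set to zero.
#'
#' @param frames numeric matrix, trials in rows, frames in columns.
#' @param frame_duration frame duration in seconds.
#' @param mu_per_trial per-trial generative mean evidence.
#' @param sigma_s nominal fluctuation magnitude.
#' @param kind one of `"gaussian"`, `"zero_integral"`, `"brightness_discs"`,
#'   `"two_pulse"`, `"ou_current"`.
#' @param seed integer seed recorded for provenance.
#' @return an object of class `dwell_stimuli`.
#' @export
new_stimuli <- function(frames, frame_duration, mu_per_trial, sigma_s, kind,
                        seed = NA_integer_) {
  stopifnot(is.matrix(frames), frame_duration > 0,
            length(mu_per_trial) == nrow(frames))
  kind <- match.arg(kind, c("gaussian", "zero_integral", "brightness_discs",
                            "two_pulse", "ou_current"))
  structure(
    list(frames = frames, frame_duration = frame_duration,
         mu_per_trial = mu_per_trial, sigma_s = sigma_s, kind = kind,
         seed = seed,
         coupling = if (kind == "brightness_discs") "drift" else "white"),
    class = "dwell_stimuli")
}

#' @export
print.dwell_stimuli <- function(x, ...) {
  cat(sprintf("<dwell_stimuli> kind=%s  %d trials x %d frames (%.4g s each, T = %.3g s)\n",
              x$kind, nrow(x$frames), ncol(x$frames), x$frame_duration,
              ncol(x$frames) * x$frame_duration))
  cat(sprintf("  sigma_s = %.4g, mean(mu_i) = %.4g, coupling = %s\n",
              x$sigma_s, mean(x$mu_per_trial), x$coupling))
  invisible(x)
}

#' Gaussian frame stimuli
#'
#' Independent Gaussian evidence per frame, `S ~ N(mu, sigma_s^2)`, the
#' discrete equivalent of a constant drift plus white stimulus noise.
#'
#' @param n_trials,n_frames ensemble dimensions.
#' @param mu mean evidence per trial (scalar, or vector of length `n_trials`).
#' @param sigma_s per-frame fluctuation standard deviation (>= 0).
#' @param frame_duration frame duration in seconds (default 5 ms, the
#'   integrator step tau/40 at tau = 200 ms).
#' @param seed integer seed (stimulus substream).
#' @return a [new_stimuli()] object of kind `"gaussian"`.
#' @export
gaussian_frames <- function(n_trials, n_frames, mu, sigma_s, seed,
                            frame_duration = 0.005) {
  if (sigma_s < 0) stop("sigma_s must be non-negative")
  if (n_frames < 1) stop("n_frames must be >= 1")
  mu <- rep_len(mu, n_trials)
  fr <- with_substream(seed, "stimulus", {
    matrix(stats::rnorm(n_trials * n_frames, 0, sigma_s), n_trials, n_frames)
  })
  fr <- fr + mu
  new_stimuli(fr, frame_duration, mu, sigma_s, "gaussian", seed)
}

#' Stimuli with exactly zero integrated evidence
#'
#' Each row of Gaussian draws is z-scored (population standard deviation, so
#' that two frames give exactly +/- sigma_s) and rescaled: the row mean is
#' exactly 0 and the row's population standard deviation exactly `sigma_s`.
#' Used for the double-pass consistency protocol, where any non-zero
#' integrated evidence would trivially inflate consistency.
#'
#' A degenerate draw with zero sample variance (probability zero for
#' continuous draws, but guarded anyway) is redrawn from the next substream
#' counter with a message.
#'
#' @inheritParams gaussian_frames
#' @export
zero_integral_frames <- function(n_trials, n_frames, sigma_s, seed,
                                 frame_duration = 0.005) {
  if (n_frames < 2) stop("n_frames must be >= 2 to z-score")
  if (sigma_s < 0) stop("sigma_s must be non-negative")
  fr <- matrix(NA_real_, n_trials, n_frames)
  counter <- 0L
  need <- seq_len(n_trials)
  while (length(need) > 0L) {
    y <- with_substream(seed, "stimulus", {
      matrix(stats::rnorm(length(need) * n_frames), length(need), n_frames)
    }, counter = counter)
    ctr <- y - rowMeans(y)
    sds <- sqrt(rowMeans(ctr^2))        # population sd
    ok <- sds > 0
    if (any(!ok)) message(sprintf("%d degenerate zero-variance draws; redrawing", sum(!ok)))
    if (any(ok)) {
      fr[need[ok], ] <- sigma_s * ctr[ok, , drop = FALSE] / sds[ok]
    }
    need <- need[!ok]
    counter <- counter + 1L
  }
  new_stimuli(fr, frame_duration, rep(0, n_trials), sigma_s, "zero_integral", seed)
}

#' Two-disc brightness stimuli with compensated evidence pulses
#'
#' Emulates the structure of a brightness-discrimination experiment: 100 ms
#' frames, the trial divided into five equal-length segments, and in a
#' fraction `pulse_prob` of trials a congruent or incongruent evidence pulse
#' added to one random segment and compensated equally across the remaining
#' segments, so the trial-mean net evidence always equals the generative mean
#' (and segment deviations are anticorrelated).
#'
#' The returned frames are the net evidence trace (right minus left disc).
#' `mu_per_trial` records the signed generative mean gap; subtract it (as
#' [compute_pk()] does) to recover the zero-mean fluctuation trace.
#'
#' @param n_trials number of trials.
#' @param duration_s trial duration in seconds; must give a frame count
#'   divisible by 5 (e.g. 1, 2, 3, 5 s).
#' @param gen_mean_gap generative mean difference between the discs; the sign
#'   is randomized per trial (positive = rightward).
#' @param frame_sd per-frame standard deviation of the net evidence.
#' @param pulse_prob fraction of trials carrying a pulse, in `[0, 1]`.
#' @param pulse_size absolute size of the segment-mean pulse; sign (congruent
#'   or incongruent) is randomized.
#' @param seed integer seed.
#' @export
brightness_disc_frames <- function(n_trials, duration_s,
                                   gen_mean_gap = 0.05, frame_sd = 0.3,
                                   pulse_prob = 0.8, pulse_size = 0.2,
                                   seed = 1L) {
  if (pulse_prob < 0 || pulse_prob > 1) stop("pulse_prob must be in [0, 1]")
  frame_duration <- 0.1
  n_frames <- round(duration_s / frame_duration)
  if (abs(n_frames * frame_duration - duration_s) > 1e-9 || n_frames %% 5L != 0L) {
    stop("duration_s must be a multiple of 0.5 s (five equal segments of 100 ms frames)")
  }
  per_seg <- n_frames %/% 5L
  with_substream(seed, "stimulus", {
    side <- sample(c(-1, 1), n_trials, replace = TRUE)
    mu_i <- side * gen_mean_gap
    seg_means <- matrix(rep(mu_i, 5L), n_trials, 5L)
    has_pulse <- stats::runif(n_trials) < pulse_prob
    pulse_seg <- sample.int(5L, n_trials, replace = TRUE)
    pulse_sign <- sample(c(-1, 1), n_trials, replace = TRUE)
    for (i in which(has_pulse)) {
      p <- pulse_sign[i] * pulse_size
      seg_means[i, pulse_seg[i]] <- seg_means[i, pulse_seg[i]] + p
      seg_means[i, -pulse_seg[i]] <- seg_means[i, -pulse_seg[i]] - p / 4
    }
    fr <- seg_means[, rep(seq_len(5L), each = per_seg), drop = FALSE] +
      matrix(stats::rnorm(n_trials * n_frames, 0, frame_sd), n_trials, n_frames)
    new_stimuli(fr, frame_duration, mu_i, frame_sd, "brightness_discs", seed)
  })
}

#' Condition table for the two-pulse motion design
#'
#' Enumerates the single-pulse coherence levels and the crossing of two-pulse
#' coherence sequences with delays, always with congruent motion direction.
#'
#' @param coherences two-pulse coherence levels in percent.
#' @param single_coherences single-pulse coherence levels in percent.
#' @param delays_ms inter-pulse delays in milliseconds.
#' @param n_per_condition trials planned per (sequence, delay) cell.
#' @return data.frame with columns `coh1`, `coh2` (NA for single pulses),
#'   `delay_ms`, `n`.
#' @export
two_pulse_design <- function(coherences = c(3.2, 6.4, 12.8),
                             single_coherences = c(0, 3.2, 6.4, 12.8, 25.6, 51.2),
                             delays_ms = c(0, 120, 360, 1080),
                             n_per_condition = 100L) {
  if (any(coherences < 0) || any(single_coherences < 0)) {
    stop("coherences must be non-negative")
  }
  singles <- data.frame(coh1 = single_coherences, coh2 = NA_real_,
                        delay_ms = NA_real_, n = n_per_condition)
  doubles <- expand.grid(coh1 = coherences, coh2 = coherences,
                         delay_ms = delays_ms, KEEP.OUT.ATTRS = FALSE)
  doubles$n <- n_per_condition
  rbind(singles, doubles)
}

#' Ornstein-Uhlenbeck stimulus currents for the spiking network
#'
#' Two independent OU traces with means `I0 * (1 +/- mu)` and stationary
#' standard deviation `sigma_s`, autocorrelation time `tau_stim_ms`. Uses the
#' exact OU transition density for the update (not Euler), so the stationary
#' moments hold at any step size.
#'
#' @param mu mean stimulus-difference fraction (evidence for A over B).
#' @param sigma_s stationary fluctuation amplitude (pA).
#' @param tau_stim_ms OU correlation time in ms (default 20).
#' @param duration_s trace duration in seconds.
#' @param dt_ms step in ms.
#' @param I0 baseline current (pA).
#' @param seed integer seed.
#' @return list with `t_s`, matrices are vectors `I_A`, `I_B` (pA), and the
#'   parameters.
#' @export
ou_currents <- function(mu, sigma_s, tau_stim_ms = 20, duration_s, dt_ms = 0.1,
                        I0 = 50, seed = 1L) {
  if (tau_stim_ms <= 0) stop("tau_stim must be positive")
  n <- round(duration_s * 1000 / dt_ms)
  a <- exp(-dt_ms / tau_stim_ms)
  b <- sigma_s * sqrt(1 - a^2)
  with_substream(seed, "stimulus", {
    zA <- zB <- numeric(n)
    eA <- stats::rnorm(n); eB <- stats::rnorm(n)
    zA[1] <- sigma_s * eA[1]; zB[1] <- sigma_s * eB[1]
    for (k in seq_len(n - 1L)) {
      zA[k + 1L] <- a * zA[k] + b * eA[k + 1L]
      zB[k + 1L] <- a * zB[k] + b * eB[k + 1L]
    }
    list(t_s = (seq_len(n) - 0.5) * dt_ms / 1000,
         I_A = I0 * (1 + mu) + zA, I_B = I0 * (1 - mu) + zB,
         I0 = I0, mu = mu, sigma_s = sigma_s, tau_stim_ms = tau_stim_ms,
         dt_ms = dt_ms, seed = seed)
  })
}

#' Write / read a stimulus ensemble as CSV plus JSON sidecar
#'
#' The CSV holds the trial-by-frame matrix with a header row of frame-center
#' times; the sidecar (same path with extension `.json`) holds the metadata
#' needed to reconstruct the object.
#'
#' @param x a `dwell_stimuli` object.
#' @param path CSV path.
#' @return `write_stimuli` returns `path` invisibly; `read_stimuli` the object.
#' @export
write_stimuli <- function(x, path) {
  stopifnot(inherits(x, "dwell_stimuli"))
  m <- x$frames
  colnames(m) <- sprintf("t_%.6g", (seq_len(ncol(m)) - 0.5) * x$frame_duration)
  utils::write.csv(m, path, row.names = FALSE)
  meta <- x[c("frame_duration", "mu_per_trial", "sigma_s", "kind", "seed")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  new_stimuli(unname(m), meta$frame_duration, meta$mu_per_trial, meta$sigma_s,
              meta$kind, meta$seed)
}
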