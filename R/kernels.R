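#' Rank-based AUROC between two samples
#'
#' Area under the ROC curve computed from midranks (Mann-Whitney statistic),
#' equal to `P(X > Y) + 0.5 * P(X = Y)` for X drawn from `x` and Y from `y`.
#'
#' @param x,y numeric samples (x = "rightward-choice" group).
#' @keywords internal
auroc <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Psychophysical kernel by ROC reverse correlation
#'
#' For each frame time, the AUROC between the distributions of stimulus
#' fluctuations conditioned on the eventual choice (rightward vs leftward).
#' The per-trial generative mean is subtracted first, so the two conditional
#' distributions are not trivially separated by the signal. Values near 0.5
#' mean no influence of that frame on the choice.
#'
#' @param stimuli a [new_stimuli()] ensemble.
#' @param choices vector of +/-1 choices, one per trial.
#' @param bin_s optional bin width in seconds; consecutive frames are averaged
#'   into bins of this width before the ROC analysis (must be a multiple of
#'   the frame duration). Useful when frames live on the fine integrator grid;
#'   tau/10 is a sensible default for such stimuli.
#' @return object of class `pk_kernel` with `pk` (AUROC per bin), `times`
#'   (bin centers, seconds), `n_trials`, and optionally `sem` (see
#'   [bootstrap_pk()]).
#' @export
compute_pk <- function(stimuli, choices, bin_s = NULL) {
  stopifnot(inherits(stimuli, "dwell_stimuli"),
            length(choices) == nrow(stimuli$frames))
  right <- choices > 0
  if (sum(right) < 2 || sum(!right) < 2) {
    stop("undefined kernel: need at least 2 trials of each choice")
  }
  fl <- stimuli$frames - stimuli$mu_per_trial
  fd <- stimuli$frame_duration
  if (!is.null(bin_s)) {
    k <- bin_s / fd
    if (abs(k - round(k)) > 1e-8) stop("bin_s must be a multiple of the frame duration")
    k <- as.integer(round(k))
    nb <- ncol(fl) %/% k
    fl <- sapply(seq_len(nb), function(b) {
      rowMeans(fl[, ((b - 1L) * k + 1L):(b * k), drop = FALSE])
    })
    fd <- fd * k
  }
  pk <- apply(fl, 2L, function(col) auroc(col[right], col[!right]))
  structure(list(pk = pk, times = (seq_along(pk) - 0.5) * fd,
                 bin_s = fd, n_trials = length(choices), sem = NULL),
            class = "pk_kernel")
}

#' @export
print.pk_kernel <- function(x, ...) {
  cat(sprintf("<pk_kernel> %d bins of %.4g s, %d trials; mean PK = %.3f\n",
              length(x$pk), x$bin_s, x$n_trials, mean(x$pk)))
  invisible(x)
}

#' @export
plot.pk_kernel <- function(x, ...) {
  graphics::plot(x$times, x$pk, type = "o", pch = 16, xlab = "time (s)",
                 ylab = "PK (AUROC)", ylim = range(c(x$pk, 0.4, 0.6)), ...)
  if (!is.null(x$sem)) {
    graphics::arrows(x$times, x$pk - x$sem, x$times, x$pk + x$sem,
                     angle = 90, code = 3, length = 0.02)
  }
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Normalized psychophysical-kernel area
#'
#' Trapezoidal integral of `PK(t) - 0.5`, normalized by the same integral for
#' a reference kernel: the ideal observer (perfect integrator with zero
#' internal noise) run on the same stimulus ensemble. 1 means the stimulus
#' fluctuations are integrated as well as an ideal observer; 0 means they have
#' no impact.
#'
#' @param result kernel under study ([compute_pk()] output).
#' @param reference ideal-observer kernel on the same stimulus ensemble.
#' @export
npka <- function(result, reference) {
  num <- pracma::trapz(result$times, result$pk - 0.5)
  den <- pracma::trapz(reference$times, reference$pk - 0.5)
  if (den <= 0) stop("reference kernel area must be positive")
  num / den
}

#' Normalized psychophysical-kernel slope
#'
#' The kernel is first normalized to unit area, then fit with a straight line
#' whose slope is scaled by `k = 1/(2 var(t))` (population variance of the bin
#' centers) so that the index maps a purely decaying kernel to -1 (primacy)
#' and a purely rising one to +1 (recency); a flat kernel gives 0.
#'
#' @param result a `pk_kernel`.
#' @return the normalized slope (scalar).
#' @export
pk_slope <- function(result) {
  t <- result$times
  if (length(t) < 2) stop("need at least 2 bins for a slope")
  area <- pracma::trapz(t, result$pk - 0.5)
  if (abs(area) < .Machine$double.eps^0.5) {
    stop("zero-area kernel: slope undefined")
  }
  npk <- (result$pk - 0.5) / area
  vt <- mean((t - mean(t))^2)           # population variance of bin centers
  lm_slope <- sum((t - mean(t)) * (npk - mean(npk))) / (length(t) * vt)
  k <- 1 / (2 * vt)
  raw <- lm_slope / k
  # kernels with a lobe of opposite sign can push the index slightly past the
  # nominal interval; the index is defined on (-1, 1), so saturate and keep
  # the raw value as an attribute
  structure(max(-1, min(1, raw)), raw = raw)
}

#' Bootstrap standard errors for the psychophysical kernel
#'
#' Trial-level resampling with replacement (stimulus and choice resampled
#' jointly); the per-bin standard deviation of the resampled kernels is the
#' standard error band.
#'
#' @inheritParams compute_pk
#' @param n_boot number of bootstrap repetitions (>= 100).
#' @param seed integer seed.
#' @return the `pk_kernel` with `sem` filled in, plus `boot_slopes` (the
#'   normalized slope of each resample, for slope inference).
#' @export
bootstrap_pk <- function(stimuli, choices, n_boot = 1000L, seed = 1L,
                         bin_s = NULL) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  base <- compute_pk(stimuli, choices, bin_s = bin_s)
  n <- length(choices)
  mat <- matrix(NA_real_, n_boot, length(base$pk))
  slopes <- numeric(n_boot)
  with_substream(seed, "bootstrap", {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      st <- stimuli
      st$frames <- stimuli$frames[idx, , drop = FALSE]
      st$mu_per_trial <- stimuli$mu_per_trial[idx]
      pk_b <- tryCatch(compute_pk(st, choices[idx], bin_s = bin_s),
                       error = function(e) NULL)
      if (is.null(pk_b)) next
      mat[b, ] <- pk_b$pk
      slopes[b] <- tryCatch(pk_slope(pk_b), error = function(e) NA_real_)
    }
  })
  base$sem <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  base$boot_slopes <- slopes[!is.na(slopes)]
  base
}
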