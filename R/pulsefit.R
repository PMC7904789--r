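#' Predicted accuracy for single- and double-pulse trials
#'
#' Closed-form accuracy of the double-well attractor model for brief motion
#' pulses, built from the two-state Kramers chain. For a single 120 ms pulse
#' at coherence `coh` (percent), the drift is `mu = k * coh` and
#' `P1 = P0 (1 - p_E) + (1 - P0) p_C`, with the first-visit probability from
#' the erf closed form at `x0 = 0` and the transition probabilities over
#' `T = pulse_s / tau`. For a double pulse the output of the first pulse is
#' chained through a second 120 ms pulse at `mu = k * coh2`; the delay between
#' pulses does not enter (transitions during the delay are assumed absent and
#' validated separately by [delay_robustness()]).
#'
#' When the tilt exceeds the saddle-node value (no barrier; only the largest
#' single-pulse coherences get there), the accuracy is the exact splitting
#' probability between the zero-tilt attractor positions and transitions are
#' taken as absent.
#'
#' @param params named vector or list with `k` (coherence-to-drift scaling),
#'   `alpha` (barrier parameter), `sigma` (total noise), `tau` (seconds).
#' @param coh1,coh2 pulse coherences in percent; `coh2 = NA` for single-pulse.
#' @param pulse_s pulse duration in seconds (default 0.120).
#' @return predicted probability correct (vectorized over `coh1`/`coh2`).
#' @export
predict_pulse_accuracy <- function(params, coh1, coh2 = NA, pulse_s = 0.120) {
  params <- as.list(params)
  n <- max(length(coh1), length(coh2))
  coh1 <- rep_len(coh1, n); coh2 <- rep_len(coh2, n)
  vapply(seq_len(n), function(i) {
    p1 <- pulse_state_update(NA_real_, params, coh1[i], pulse_s)
    if (is.na(coh2[i])) p1 else pulse_state_update(p1, params, coh2[i], pulse_s)
  }, numeric(1))
}

# Advance the probability of occupying the correct attractor through one
# pulse. p_correct_in = NA signals the first pulse of a trial (start x0 = 0,
# so the pulse's own first-visit probability seeds the chain); otherwise the
# pulse acts on the current attractor occupancy.
pulse_state_update <- function(p_correct_in, params, coh, pulse_s) {
  mu <- params$k * coh
  a <- params$alpha
  Tt <- pulse_s / params$tau
  if (mu < saddle_node_mu(a) * 0.999) {
    pot <- potential_spec("double_well", mu = mu, alpha = a)
    tp <- trial_transition_probs(transition_rates(pot, params$sigma), Tt)
    start <- if (is.na(p_correct_in)) {
      first_visit_probability(pot, params$sigma, x0 = 0)
    } else p_correct_in
    start * (1 - tp[["p_E"]]) + (1 - start) * tp[["p_C"]]
  } else {
    # no barrier at this tilt: accuracy is the exact splitting probability
    # between the zero-tilt attractor positions; the correcting "transition"
    # from the error side follows the same roll-down, the error one is
    # impossible
    xs <- sqrt(a / 2)
    pot <- potential_spec("double_well", mu = mu, alpha = a)
    phimax <- max(potential_value(pot, seq(-xs, xs, length.out = 512)))
    psi <- function(x) exp(2 * (potential_value(pot, x) - phimax) / params$sigma^2)
    num <- stats::integrate(psi, -xs, 0, rel.tol = 1e-9)$value
    den <- stats::integrate(psi, -xs, xs, rel.tol = 1e-9)$value
    p_up <- num / den
    if (is.na(p_correct_in)) p_up else p_correct_in + (1 - p_correct_in) * p_up
  }
}

#' Fit the double-well model to two-pulse accuracy data by maximum likelihood
#'
#' The central estimator of the package. Takes a condition table of trial
#' counts for single- and double-pulse motion-discrimination conditions and
#' fits the four parameters of the reduced double-well model -- the
#' coherence-to-drift scaling `k`, the barrier parameter `alpha`, the total
#' noise `sigma = sqrt(sigma_I^2 + sigma_S^2)`, and the time constant `tau`
#' (seconds) -- by maximizing the binomial log-likelihood
#' `sum_i [N_C,i log P_i + N_E,i log(1 - P_i)]` with Nelder-Mead from multiple
#' Latin-hypercube starting points. (A published variant of the objective,
#' the linear form `sum N_C P + N_E (1 - P)`, is available via
#' `form = "printed"` for comparison only; it is not a log-likelihood and has
#' degenerate optima at P in {0, 1}.)
#'
#' Conditions are pooled across delays per coherence sequence, reflecting the
#' empirical delay-independence of accuracy. 95% confidence intervals are
#' `+/- 1.96 * sqrt(diag(H^-1))` with `H` the finite-difference Hessian of the
#' negative log-likelihood at the optimum.
#'
#' @param data data.frame with columns `coh1`, `coh2` (NA for single-pulse),
#'   `n_trials`, `n_correct`, and optionally `delay_ms` (pooled over).
#' @param init optional named start values `c(k, alpha, sigma, tau)`.
#' @param lower,upper named bounds used for the Latin-hypercube restarts (and
#'   as box constraints via log-parameterization limits).
#' @param n_restarts Nelder-Mead restarts (default 10).
#' @param maxit iteration cap per restart (the final polish gets twice this).
#' @param pulse_s pulse duration in seconds.
#' @param form `"binomial"` (the log-likelihood) or `"printed"`.
#' @param seed seed for the Latin-hypercube starting points.
#' @return object of class `dwm_fit`.
#' @export
dwm_fit <- function(data, init = NULL,
                    lower = c(k = 0.002, alpha = 0.15, sigma = 0.15, tau = 0.5),
                    upper = c(k = 0.06, alpha = 2.5, sigma = 1.5, tau = 15),
                    n_restarts = 10L, pulse_s = 0.120, maxit = 2000L,
                    form = c("binomial", "printed"), seed = 1L) {
  form <- match.arg(form)
  stopifnot(all(c("coh1", "coh2", "n_trials", "n_correct") %in% names(data)),
            all(data$n_correct <= data$n_trials))
  key <- paste(data$coh1, data$coh2)
  pooled <- data.frame(
    coh1 = tapply(data$coh1, key, `[`, 1L),
    coh2 = tapply(data$coh2, key, `[`, 1L),
    n_trials = as.vector(tapply(data$n_trials, key, sum)),
    n_correct = as.vector(tapply(data$n_correct, key, sum)),
    row.names = NULL)
  informative <- pooled$coh1 > 0 | (!is.na(pooled$coh2) & pooled$coh2 > 0)
  if (sum(informative) < 4) stop("need at least 4 informative conditions")

  nm <- c("k", "alpha", "sigma", "tau")
  # box-constrained search: Nelder-Mead runs on z with
  # param = lower + (upper - lower) * plogis(z)
  to_par <- function(z) lower[nm] + (upper[nm] - lower[nm]) * stats::plogis(z)
  to_z <- function(p) stats::qlogis(pmin(pmax((p - lower[nm]) / (upper[nm] - lower[nm]),
                                              1e-6), 1 - 1e-6))
  objective <- function(z) {
    p <- as.list(stats::setNames(to_par(z), nm))
    P <- tryCatch(
      predict_pulse_accuracy(p, pooled$coh1, pooled$coh2, pulse_s = pulse_s),
      error = function(e) rep(NA_real_, nrow(pooled)))
    if (any(!is.finite(P))) return(1e10)
    P <- pmin(pmax(P, 1e-9), 1 - 1e-9)
    if (form == "binomial") {
      -sum(pooled$n_correct * log(P) + (pooled$n_trials - pooled$n_correct) * log1p(-P))
    } else {
      -sum(pooled$n_correct * P + (pooled$n_trials - pooled$n_correct) * (1 - P))
    }
  }

  starts <- with_substream(seed, "init", {
    u <- lhs::randomLHS(n_restarts, 4L)
    t(apply(u, 1L, function(row) to_z(lower[nm] + row * (upper[nm] - lower[nm]))))
  })
  if (!is.null(init)) starts[1L, ] <- to_z(init[nm])

  best <- NULL
  trace <- data.frame(restart = seq_len(n_restarts), value = NA_real_,
                      convergence = NA_integer_)
  for (r in seq_len(n_restarts)) {
    o <- stats::optim(starts[r, ], objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    trace$value[r] <- o$value; trace$convergence[r] <- o$convergence
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value >= 1e9) {
    stop("fit failed: no restart reached a finite likelihood; trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))
  }
  # polish from the best point
  best <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2L * maxit, reltol = 1e-12))
  if (best$convergence != 0 && all(trace$convergence != 0)) {
    warning("Nelder-Mead hit the iteration limit in every restart; ",
            "estimates may not be fully converged")
  }
  est <- stats::setNames(to_par(best$par), nm)

  # finite-difference Hessian of the negative log-likelihood, natural scale
  f_nat <- function(p) objective(log(p))
  H <- fd_hessian(f_nat, est)
  # The model carries an exact scaling degeneracy: (alpha, sigma, k, tau) ->
  # (c alpha, c sigma, c^{3/2} k, c tau) leaves every condition accuracy
  # unchanged, so the Hessian has a (near-)null direction along that ridge.
  # Invert by eigendecomposition with small/negative eigenvalues floored at a
  # tiny positive value: the variance along the flat direction is then huge,
  # i.e. the Wald interval honestly reports that the data do not pin down the
  # individual parameters along the ridge (the identifiable combinations
  # alpha^2/sigma^2, k/alpha^{3/2}, alpha/tau have finite intervals).
  ei <- eigen((H + t(H)) / 2, symmetric = TRUE)
  d <- pmax(ei$values, max(abs(ei$values)) * 1e-9)
  vc <- ei$vectors %*% diag(1 / d, length(d)) %*% t(ei$vectors)
  dimnames(vc) <- list(nm, nm)
  se <- sqrt(pmax(diag(vc), 0))

  P_hat <- predict_pulse_accuracy(as.list(est), pooled$coh1, pooled$coh2,
                                  pulse_s = pulse_s)
  if (any(P_hat <= 0 | P_hat >= 1)) {
    warning("predicted accuracies clipped away from {0, 1}")
    P_hat <- pmin(pmax(P_hat, 1e-9), 1 - 1e-9)
  }
  ll <- sum(pooled$n_correct * log(P_hat) +
              (pooled$n_trials - pooled$n_correct) * log1p(-P_hat))
  pooled$predicted <- P_hat
  pooled$observed <- pooled$n_correct / pooled$n_trials

  structure(list(coefficients = est, se = se, vcov = vc,
                 ci95 = cbind(lower = est - 1.96 * se, upper = est + 1.96 * se),
                 loglik = ll, table = pooled, pulse_s = pulse_s, form = form,
                 sigma_i_max = tryCatch(
                   delay_noise_bound(est[["alpha"]], est[["tau"]], 1.08),
                   error = function(e) NA_real_),
                 optim = best, restart_trace = trace),
            class = "dwm_fit")
}

fd_hessian <- function(f, x, rel = 1e-3) {
  n <- length(x)
  h <- pmax(abs(x) * rel, 1e-6)
  H <- matrix(NA_real_, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.dwm_fit <- function(x, ...) {
  cat("Double-well attractor model fit (two-pulse accuracy data)\n")
  est <- x$coefficients
  cat(sprintf("  k = %.4g, alpha = %.4g, sigma = %.4g, tau = %.4g s\n",
              est["k"], est["alpha"], est["sigma"], est["tau"]))
  cat(sprintf("  logLik = %.2f over %d conditions;  sigma_I^max(1.08 s) = %.3g\n",
              x$loglik, nrow(x$table), x$sigma_i_max))
  invisible(x)
}

#' @export
summary.dwm_fit <- function(object, ...) {
  tab <- cbind(estimate = object$coefficients, se = object$se, object$ci95)
  out <- list(coefficients = tab, loglik = object$loglik,
              table = object$table, sigma_i_max = object$sigma_i_max)
  class(out) <- "summary.dwm_fit"
  out
}

#' @export
print.summary.dwm_fit <- function(x, ...) {
  cat("Coefficients (95% CI from inverse Hessian):\n")
  print(round(x$coefficients, 5))
  cat(sprintf("\nlogLik: %.2f\nDelay-compatible internal-noise bound sigma_I^max: %.4g\n",
              x$loglik, x$sigma_i_max))
  cat("\nCondition table:\n")
  print(transform(x$table, observed = round(observed, 4),
                  predicted = round(predicted, 4)))
  invisible(x)
}

#' @export
coef.dwm_fit <- function(object, ...) object$coefficients

#' @export
vcov.dwm_fit <- function(object, ...) object$vcov

#' @export
logLik.dwm_fit <- function(object, ...) {
  structure(object$loglik, df = 4L, class = "logLik")
}

#' @export
confint.dwm_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.dwm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$table$predicted)
  predict_pulse_accuracy(as.list(object$coefficients), newdata$coh1,
                         newdata$coh2, pulse_s = object$pulse_s)
}

#' @export
residuals.dwm_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  tab <- object$table
  r <- tab$observed - tab$predicted
  if (type == "pearson") {
    r <- r / sqrt(tab$predicted * (1 - tab$predicted) / tab$n_trials)
  }
  r
}

#' @export
plot.dwm_fit <- function(x, ...) {
  tab <- x$table
  dbl <- !is.na(tab$coh2)
  graphics::plot(tab$coh2[dbl], tab$observed[dbl],
                 pch = 16, col = as.integer(factor(tab$coh1[dbl])),
                 xlab = "coherence of second pulse (%)", ylab = "accuracy",
                 ylim = range(c(tab$observed, tab$predicted)), ...)
  for (c1 in sort(unique(tab$coh1[dbl]))) {
    sel <- dbl & tab$coh1 == c1
    o <- order(tab$coh2[sel])
    graphics::lines(tab$coh2[sel][o], tab$predicted[sel][o],
                    col = as.integer(factor(c1, sort(unique(tab$coh1[dbl])))))
  }
  graphics::legend("bottomright", legend = sprintf("coh1 = %.1f", sort(unique(tab$coh1[dbl]))),
                   col = seq_along(unique(tab$coh1[dbl])), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate condition tables from the fitted (or given) model
#'
#' Draws binomial trial counts from the closed-form condition accuracies:
#' the parametric bootstrap / synthetic-data generator for the two-pulse
#' analysis.
#'
#' @param object a `dwm_fit`, or a named parameter vector/list.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param design condition table (columns `coh1`, `coh2`, `n`), default
#'   [two_pulse_design()].
#' @param ... unused.
#' @return a list of `nsim` data.frames with `coh1`, `coh2`, `n_trials`,
#'   `n_correct` (a single data.frame if `nsim = 1`).
#' @export
simulate.dwm_fit <- function(object, nsim = 1, seed = 1L, design = NULL, ...) {
  params <- if (inherits(object, "dwm_fit")) as.list(object$coefficients) else as.list(object)
  pulse_s <- if (inherits(object, "dwm_fit")) object$pulse_s else 0.120
  if (is.null(design)) design <- two_pulse_design()
  P <- predict_pulse_accuracy(params, design$coh1, design$coh2, pulse_s = pulse_s)
  out <- with_substream(seed, "tables", {
    lapply(seq_len(nsim), function(i) {
      data.frame(coh1 = design$coh1, coh2 = design$coh2,
                 delay_ms = if ("delay_ms" %in% names(design)) design$delay_ms else NA,
                 n_trials = design$n,
                 n_correct = stats::rbinom(nrow(design), design$n, P))
    })
  })
  if (nsim == 1) out[[1]] else out
}

#' @rdname simulate.dwm_fit
#' @export
simulate_condition_table <- function(object, design = NULL, seed = 1L) {
  simulate.dwm_fit(object, nsim = 1, seed = seed, design = design)
}

#' Primacy-recency index from per-trial pulse data
#'
#' Logistic regression of the correctness of the choice on the two pulse
#' coherences, `logit(P_C) = b0 + b1 coh1 + b2 coh2`; the index is
#' `(b2 - b1) / (b1 + b2)`, -1 for pure primacy (only the first pulse
#' matters), +1 for pure recency. On (quasi-)separated data the regression is
#' refit with a small ridge penalty, with a warning.
#'
#' @param trials data.frame with `coh1`, `coh2`, `correct` (0/1) per trial.
#' @return list with `pri`, `beta1`, `beta2`.
#' @export
pri <- function(trials) {
  stopifnot(all(c("coh1", "coh2", "correct") %in% names(trials)))
  if (length(unique(trials$coh1)) < 2 || length(unique(trials$coh2)) < 2) {
    stop("both pulse coherences must vary across trials")
  }
  fit <- suppressWarnings(stats::glm(correct ~ coh1 + coh2, data = trials,
                                     family = stats::binomial()))
  b <- stats::coef(fit)[c("coh1", "coh2")]
  if (!fit$converged || any(abs(b) > 10)) {
    warning("separation detected; refitting with ridge penalty")
    X <- cbind(1, trials$coh1, trials$coh2)
    y <- trials$correct
    nll <- function(beta) {
      eta <- X %*% beta
      sum(log1p(exp(-(2 * y - 1) * eta))) + 1e-3 * sum(beta[-1]^2)
    }
    b <- stats::optim(c(0, 0.01, 0.01), nll, method = "BFGS")$par[2:3]
    names(b) <- c("coh1", "coh2")
  }
  list(pri = unname((b["coh2"] - b["coh1"]) / (b["coh1"] + b["coh2"])),
       beta1 = unname(b["coh1"]), beta2 = unname(b["coh2"]))
}

#' Simulate per-trial two-pulse outcomes from the closed-form model
#'
#' @param params named parameters `k`, `alpha`, `sigma`, `tau`.
#' @param design rows of `coh1`, `coh2`, `n` (double-pulse only for PRI use).
#' @param seed integer seed.
#' @return data.frame with one row per trial: `coh1`, `coh2`, `correct`.
#' @export
simulate_pulse_trials <- function(params, design = NULL, seed = 1L) {
  if (is.null(design)) {
    design <- two_pulse_design(n_per_condition = 1000L)
    design <- design[!is.na(design$coh2) & design$delay_ms == 0, ]
  }
  P <- predict_pulse_accuracy(as.list(params), design$coh1, design$coh2)
  with_substream(seed, "trials", {
    idx <- rep(seq_len(nrow(design)), design$n)
    data.frame(coh1 = design$coh1[idx], coh2 = design$coh2[idx],
               correct = stats::rbinom(length(idx), 1L, P[idx]))
  })
}

#' Delay robustness of the attractor model versus a perfect integrator
#'
#' Computes (i) the largest internal noise `sigma_i_max` for which the
#' analytic switch probability during the longest delay stays below
#' `threshold`, and (ii) accuracy-versus-delay curves for the double-well
#' model and for a perfect integrator carrying the evidence as a diffusing
#' analog value.
#'
#' The double-well curve chains pulse 1, a symmetric two-state relaxation
#' during the delay at internal noise `sigma_i`, and pulse 2. The perfect
#' integrator accuracy is `Phi(mu_tot * T_p / sqrt(tau * (2 T_p sigma^2 +
#' T_delay sigma_i^2)))` with `mu_PI = 0.44 k coh` per pulse (the scaling that
#' matches the attractor model at zero delay); its memory trace keeps
#' diffusing during the delay, so accuracy decreases for every delay.
#'
#' @param params named parameters `k`, `alpha`, `sigma`, `tau` (seconds).
#' @param delays_s delays to evaluate (seconds).
#' @param sigma_i internal noise used for the curves (default: the computed
#'   `sigma_i_max`).
#' @param threshold delay-switch criterion for the bound (default 0.01).
#' @param max_delay_s delay at which the bound is evaluated (default 1.08 s,
#'   the longest delay of the two-pulse design).
#' @param coh_pairs data.frame of `coh1`, `coh2` averaged over (default: the
#'   nine two-pulse sequences).
#' @return list with `sigma_i_max` and a data.frame `curves` (`delay_s`,
#'   `dwm`, `pi`).
#' @export
delay_robustness <- function(params, delays_s = seq(0, 1.08, by = 0.12),
                             sigma_i = NULL, threshold = 0.01,
                             max_delay_s = 1.08, coh_pairs = NULL) {
  params <- as.list(params)
  sim <- delay_noise_bound(params$alpha, params$tau, max_delay_s, threshold)
  if (is.null(sigma_i)) sigma_i <- sim
  if (is.null(coh_pairs)) {
    coh_pairs <- expand.grid(coh1 = c(3.2, 6.4, 12.8), coh2 = c(3.2, 6.4, 12.8))
  }
  dwm_curve <- vapply(delays_s, function(d) {
    p_sw <- delay_switch_probability(params$alpha, sigma_i, params$tau, d)
    mean(vapply(seq_len(nrow(coh_pairs)), function(i) {
      p1 <- pulse_state_update(NA, params, coh_pairs$coh1[i], 0.120)
      p1d <- p1 * (1 - p_sw) + (1 - p1) * p_sw
      pulse_state_update(p1d, params, coh_pairs$coh2[i], 0.120)
    }, numeric(1)))
  }, numeric(1))
  Tp <- 0.120
  pi_curve <- vapply(delays_s, function(d) {
    mean(stats::pnorm(
      0.44 * params$k * (coh_pairs$coh1 + coh_pairs$coh2) * Tp /
        sqrt(params$tau * (2 * Tp * params$sigma^2 + d * sigma_i^2))))
  }, numeric(1))
  list(sigma_i_max = sim, sigma_i = sigma_i,
       curves = data.frame(delay_s = delays_s, dwm = dwm_curve, pi = pi_curve))
}
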