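#' First-visit probability of the correct attractor
#'
#' Probability that a trial starting at `x0` first reaches the correct
#' attractor rather than the error attractor, for a double-well potential with
#' total noise `sigma_total = sqrt(sigma_I^2 + sigma_S^2)`.
#'
#' Two evaluation modes:
#' * `"erf"` (default): the closed form obtained by neglecting the quartic
#'   term near the origin, a ratio of error functions with argument scale
#'   `sqrt(2 alpha)/sigma` and shift `mu/(2 alpha)`.
#' * `"quadrature"`: the exact splitting probability, the ratio of integrals
#'   of `exp(2 phi(x)/sigma^2)` over `[x_E, x0]` and `[x_E, x_C]`, evaluated
#'   numerically with the integrand rescaled by its maximum for stability.
#'
#' @param potential a double-well [potential_spec()].
#' @param sigma_total total noise magnitude (> 0).
#' @param x0 starting position (default 0).
#' @param method `"erf"` or `"quadrature"`.
#' @export
first_visit_probability <- function(potential, sigma_total, x0 = 0,
                                    method = c("erf", "quadrature")) {
  method <- match.arg(method)
  stopifnot(sigma_total > 0)
  fp <- fixed_points(potential)
  a <- potential$alpha; mu <- potential$mu
  if (method == "erf") {
    erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
    s <- sqrt(2 * a) / sigma_total
    b <- mu / (2 * a)
    (erf(s * (x0 + b)) - erf(s * (fp[["x_E"]] + b))) /
      (erf(s * (fp[["x_C"]] + b)) - erf(s * (fp[["x_E"]] + b)))
  } else {
    phimax <- max(potential_value(potential, seq(fp[["x_E"]], fp[["x_C"]], length.out = 512)))
    psi <- function(x) exp(2 * (potential_value(potential, x) - phimax) / sigma_total^2)
    num <- stats::integrate(psi, fp[["x_E"]], x0, rel.tol = 1e-10)$value
    den <- stats::integrate(psi, fp[["x_E"]], fp[["x_C"]], rel.tol = 1e-10)$value
    num / den
  }
}

#' Kramers transition rates of the double-well
#'
#' Escape rates from the error attractor (`k_C`, correcting) and from the
#' correct attractor (`k_E`, error-generating), with curvature prefactor
#' `sqrt(|phi''(x_att) phi''(x_U)|)/(2 pi)` and barrier exponent
#' `-2 (phi(x_U) - phi(x_att)) / sigma^2`. Rates are per unit dimensionless
#' time `t/tau`; divide by `tau` (seconds) for rates per second.
#'
#' @inheritParams first_visit_probability
#' @return named vector `c(k_C, k_E)` (per unit `t/tau`).
#' @export
transition_rates <- function(potential, sigma_total) {
  fp <- fixed_points(potential)
  cu <- potential_curvature(potential, fp)
  ph <- potential_value(potential, fp)
  pref_C <- sqrt(abs(cu[["x_E"]] * cu[["x_U"]])) / (2 * pi)
  pref_E <- sqrt(abs(cu[["x_C"]] * cu[["x_U"]])) / (2 * pi)
  k_C <- pref_C * exp(-2 * (ph[["x_U"]] - ph[["x_E"]]) / sigma_total^2)
  k_E <- pref_E * exp(-2 * (ph[["x_U"]] - ph[["x_C"]]) / sigma_total^2)
  c(k_C = k_C, k_E = k_E)
}

#' Per-trial transition probabilities of the two-state chain
#'
#' For total rate `k = k_C + k_E` and stationary accuracy
#' `P_inf = k_C / k`, the probability of making a correcting
#' (error-generating) transition within a trial of duration `T` (in units of
#' `tau`) is `p_C = P_inf (1 - exp(-kT))` (`p_E = (1 - P_inf)(1 - exp(-kT))`).
#'
#' @param rates named vector from [transition_rates()].
#' @param T_over_tau trial duration in units of tau (>= 0).
#' @return named vector `c(p_C, p_E, p_inf)`.
#' @export
trial_transition_probs <- function(rates, T_over_tau) {
  if (T_over_tau < 0) stop("T must be non-negative")
  k <- rates[["k_C"]] + rates[["k_E"]]
  p_inf <- if (k > 0) rates[["k_C"]] / k else 0.5
  q <- 1 - exp(-k * T_over_tau)
  c(p_C = p_inf * q, p_E = (1 - p_inf) * q, p_inf = p_inf)
}

#' Analytic accuracy of the double-well attractor model
#'
#' Chains the first-visit probability through the two-state Kramers chain:
#' `P = P_0 (1 - p_E) + (1 - P_0) p_C`, algebraically equal to
#' `P_0 exp(-kT) + P_inf (1 - exp(-kT))`. Both forms are computed and checked
#' to agree to 1e-12.
#'
#' @inheritParams first_visit_probability
#' @param T_over_tau stimulus duration in units of tau.
#' @param p0_method passed to [first_visit_probability()].
#' @return object of class `kramers_prediction`: list with `p0`, `k_c`, `k_e`,
#'   `p_c`, `p_e`, `p_inf`, `accuracy`, `fixed_points`, `barrier_c`,
#'   `barrier_e` (barrier heights seen from the correct/error attractor) and
#'   `kramers_valid` (smallest barrier >= 2 sigma^2).
#' @export
kramers_accuracy <- function(potential, sigma_total, T_over_tau, x0 = 0,
                             p0_method = c("erf", "quadrature")) {
  p0 <- first_visit_probability(potential, sigma_total, x0, method = p0_method)
  rates <- transition_rates(potential, sigma_total)
  tp <- trial_transition_probs(rates, T_over_tau)
  P1 <- p0 * (1 - tp[["p_E"]]) + (1 - p0) * tp[["p_C"]]
  ekT <- exp(-(rates[["k_C"]] + rates[["k_E"]]) * T_over_tau)
  P2 <- p0 * ekT + tp[["p_inf"]] * (1 - ekT)
  if (abs(P1 - P2) > 1e-12) stop("two-state accuracy forms disagree")
  fp <- fixed_points(potential)
  ph <- potential_value(potential, fp)
  barrier_e <- ph[["x_U"]] - ph[["x_E"]]
  barrier_c <- ph[["x_U"]] - ph[["x_C"]]
  structure(list(p0 = p0, k_c = rates[["k_C"]], k_e = rates[["k_E"]],
                 p_c = tp[["p_C"]], p_e = tp[["p_E"]], p_inf = tp[["p_inf"]],
                 accuracy = P1, fixed_points = fp,
                 barrier_c = barrier_c, barrier_e = barrier_e,
                 kramers_valid = min(barrier_c, barrier_e) >= 2 * sigma_total^2,
                 sigma_total = sigma_total, T_over_tau = T_over_tau,
                 potential = potential),
            class = "kramers_prediction")
}

#' @export
print.kramers_prediction <- function(x, ...) {
  cat(sprintf("<kramers_prediction> mu = %.4g, alpha = %.4g, sigma = %.4g, T = %.4g tau\n",
              x$potential$mu, x$potential$alpha, x$sigma_total, x$T_over_tau))
  cat(sprintf("  P0 = %.4f  p_C = %.4f  p_E = %.4f  P_inf = %.4f  P = %.4f%s\n",
              x$p0, x$p_c, x$p_e, x$p_inf, x$accuracy,
              if (x$kramers_valid) "" else "  [outside Kramers validity]"))
  invisible(x)
}

#' Switch probability during a stimulus-free memory delay
#'
#' With zero tilt during the delay the two attractors are symmetric and only
#' internal noise drives transitions; the occupancy of the initially chosen
#' attractor relaxes to 1/2, so the probability of having switched after a
#' delay `d` is `0.5 * (1 - exp(-2 k_sym d / tau))`, with `k_sym` the
#' symmetric Kramers rate at `mu = 0` and noise `sigma_i`.
#'
#' @param alpha barrier parameter.
#' @param sigma_i internal noise during the delay.
#' @param tau_s integrator time constant in seconds.
#' @param delay_s delay duration in seconds.
#' @export
delay_switch_probability <- function(alpha, sigma_i, tau_s, delay_s) {
  if (sigma_i <= 0) return(0)
  k_sym <- transition_rates(potential_spec("double_well", mu = 0, alpha = alpha),
                            sigma_i)[["k_C"]]
  0.5 * (1 - exp(-2 * k_sym * delay_s / tau_s))
}

#' Largest internal noise compatible with a quiet memory delay
#'
#' Root-finds the internal-noise magnitude at which the analytic
#' [delay_switch_probability()] over the given delay equals `threshold`
#' (default 1%).
#'
#' @inheritParams delay_switch_probability
#' @param threshold switch-probability criterion in (0, 1).
#' @export
delay_noise_bound <- function(alpha, tau_s, delay_s, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  f <- function(s) delay_switch_probability(alpha, s, tau_s, delay_s) - threshold
  stats::uniroot(f, lower = 1e-4, upper = 5, tol = 1e-10)$root
}

#' Locate the interior maximum of the accuracy-versus-fluctuation curve
#'
#' Numerical argmax of the analytic accuracy over a sigma grid, refined by
#' golden-section search. Returns NA when the curve is monotone on the grid
#' (no interior maximum), which happens for `mu > mu_C(alpha)`.
#'
#' @inheritParams kramers_accuracy
#' @param sigma_range search interval for the total noise.
#' @param n_grid coarse-grid size.
#' @return list with `sigma_star` (or NA) and the grid scan.
#' @export
accuracy_peak <- function(potential, T_over_tau, sigma_range = c(0.1, 1),
                          n_grid = 60L) {
  sg <- seq(sigma_range[1], sigma_range[2], length.out = n_grid)
  acc <- vapply(sg, function(s)
    kramers_accuracy(potential, s, T_over_tau)$accuracy, numeric(1))
  i <- which(diff(sign(diff(acc))) == -2) + 1L   # interior local maxima
  if (length(i) == 0) {
    return(list(sigma_star = NA_real_, sigma = sg, accuracy = acc))
  }
  i <- i[which.max(acc[i])]
  opt <- stats::optimize(function(s)
    kramers_accuracy(potential, s, T_over_tau)$accuracy,
    lower = sg[max(1L, i - 1L)], upper = sg[min(n_grid, i + 1L)], maximum = TRUE,
    tol = 1e-8)
  list(sigma_star = opt$maximum, accuracy_star = opt$objective,
       sigma = sg, accuracy = acc)
}
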