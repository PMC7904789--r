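#' Potential landscapes for the diffusion models
#'
#' The decision variable obeys `tau dx/dt = -phi'(x) + noise`. Three families:
#'
#' * `linear`: `phi(x) = -mu * x` (constant drift; with bounds this is the
#'   classic drift-diffusion model).
#' * `flat`: `phi(x) = 0` (perfect integrator; the stimulus mean enters only
#'   through the stimulus term).
#' * `double_well`: `phi(x) = -mu*x - alpha*x^2 + x^4`, two attractors
#'   separated by a barrier of height `alpha^2/4` (at `mu = 0`).
#'
#' Note on sign conventions: some treatments write the quadratic coefficient
#' as `c2 = -alpha`, so a published `c2 = -0.8` corresponds to `alpha = 0.8`
#' here; a barrier exists for `alpha > 0`.
#'
#' @param family `"linear"`, `"flat"` or `"double_well"`.
#' @param mu mean drift / tilt of the potential.
#' @param alpha barrier parameter (double-well only, > 0 for bistability).
#' @return object of class `potential_spec`.
#' @export
potential_spec <- function(family = c("double_well", "linear", "flat"),
                           mu = 0, alpha = NULL) {
  family <- match.arg(family)
  if (family == "double_well") {
    if (is.null(alpha)) stop("double_well potential requires alpha")
  } else {
    alpha <- NULL
  }
  structure(list(family = family, mu = mu, alpha = alpha),
            class = "potential_spec")
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec> %s: mu = %.4g%s\n", x$family, x$mu,
              if (x$family == "double_well") sprintf(", alpha = %.4g", x$alpha) else ""))
  invisible(x)
}

#' Potential value, drift force, and curvature
#'
#' `drift_force` returns `-phi'(x)` analytically: `mu` (linear), `0` (flat),
#' `mu + 2*alpha*x - 4*x^3` (double-well). `potential_value` returns `phi(x)`
#' and `potential_curvature` returns `phi''(x)`.
#'
#' @param potential a [potential_spec()].
#' @param x positions (vectorized).
#' @export
drift_force <- function(potential, x) {
  switch(potential$family,
         linear = rep(potential$mu, length(x)),
         flat = rep(0, length(x)),
         double_well = potential$mu + 2 * potential$alpha * x - 4 * x^3)
}

#' @rdname drift_force
#' @export
potential_value <- function(potential, x) {
  switch(potential$family,
         linear = -potential$mu * x,
         flat = rep(0, length(x)),
         double_well = -potential$mu * x - potential$alpha * x^2 + x^4)
}

#' @rdname drift_force
#' @export
potential_curvature <- function(potential, x) {
  switch(potential$family,
         linear = rep(0, length(x)),
         flat = rep(0, length(x)),
         double_well = -2 * potential$alpha + 12 * x^2)
}

#' Fixed points of the double-well potential
#'
#' Real roots of `phi'(x) = 0`, i.e. of the cubic `mu + 2*alpha*x - 4*x^3`,
#' sorted, returned as `(x_E, x_U, x_C)` for `mu >= 0` (error attractor,
#' unstable point, correct attractor). Errors if the tilt exceeds the
#' saddle-node value `mu_sn = (4*alpha/3) * sqrt(alpha/6)` at which the
#' barrier disappears.
#'
#' @param potential a double-well [potential_spec()].
#' @return named numeric vector `c(x_E, x_U, x_C)`.
#' @export
fixed_points <- function(potential) {
  if (potential$family != "double_well") stop("fixed points require a double-well potential")
  a <- potential$alpha; mu <- potential$mu
  if (a <= 0 || abs(mu) >= saddle_node_mu(a)) {
    stop("single-well regime: no barrier (|mu| >= saddle-node tilt or alpha <= 0)")
  }
  r <- polyroot(c(mu, 2 * a, 0, -4))
  r <- sort(Re(r[abs(Im(r)) < 1e-8 * max(1, abs(r))]))
  if (length(r) != 3L) stop("expected three real fixed points")
  stats::setNames(r, c("x_E", "x_U", "x_C"))
}

#' Critical tilt values of the double-well
#'
#' `critical_mu` is the tilt above which the accuracy-versus-fluctuation curve
#' loses its interior maximum, `mu_C = (alpha/2) * sqrt(alpha/2)`.
#' `saddle_node_mu` is the larger tilt at which the two wells merge and the
#' barrier disappears.
#'
#' @param alpha barrier parameter (> 0).
#' @export
critical_mu <- function(alpha) {
  if (any(alpha <= 0)) stop("no barrier: alpha must be positive")
  (alpha / 2) * sqrt(alpha / 2)
}

#' @rdname critical_mu
#' @export
saddle_node_mu <- function(alpha) {
  if (any(alpha <= 0)) stop("no barrier: alpha must be positive")
  (4 * alpha / 3) * sqrt(alpha / 6)
}
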