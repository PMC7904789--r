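#' Parameters of the n-choice winner-take-all rate network
#'
#' `n` excitatory populations with self-excitation `s`, competing through a
#' shared inhibitory population (coupling `c` onto excitatory units, `g/n`
#' from each excitatory unit onto the inhibitory one), driven by inputs
#' `I_i = I +/- fractions of dI` (population 1 gets the extra share) plus
#' Gaussian white noise of amplitude `sigma` on the excitatory units and
#' `sigma_i_pop` on the inhibitory one. The transfer function is piecewise:
#' 0 for x < 0, x^2 on [0, 1], 2*sqrt(x - 3/4) for x > 1 (continuous and
#' increasing).
#'
#' @param n_choices 3 or 4.
#' @param s self-excitation (default 0.694).
#' @param c_inh,g inhibitory couplings (default sqrt(5)).
#' @param tau_ms,tau_i_ms excitatory / inhibitory time constants (20, 10 ms).
#' @param I baseline input (default 2.25).
#' @param dI input advantage of population 1 (default `0.03 * s`).
#' @param sigma excitatory noise amplitude.
#' @param sigma_i_pop inhibitory noise amplitude (default 0).
#' @param favored index of the population receiving the input advantage
#'   (default 1; a trial is correct when this population wins).
#' @export
ratenet_params <- function(n_choices = 3L, s = 0.694, c_inh = sqrt(5),
                           g = sqrt(5), tau_ms = 20, tau_i_ms = 10,
                           I = 2.25, dI = 0.03 * 0.694, sigma = 0.18,
                           sigma_i_pop = 0, favored = 1L) {
  if (!n_choices %in% c(3L, 4L)) stop("n_choices must be 3 or 4")
  if (!favored %in% seq_len(n_choices)) stop("favored must index a population")
  structure(list(n = as.integer(n_choices), s = s, c_inh = c_inh, g = g,
                 tau_ms = tau_ms, tau_i_ms = tau_i_ms, I = I, dI = dI,
                 sigma = sigma, sigma_i_pop = sigma_i_pop,
                 favored = as.integer(favored)),
            class = "ratenet_params")
}

#' Piecewise transfer function of the rate network
#'
#' @param x input (vectorized).
#' @export
ratenet_transfer <- function(x) {
  out <- numeric(length(x))
  mid <- x >= 0 & x <= 1
  hi <- x > 1
  out[mid] <- x[mid]^2
  out[hi] <- 2 * sqrt(x[hi] - 3 / 4)
  out
}

#' Simulate the n-choice rate network and report accuracy
#'
#' Euler integration (0.1 ms step by default) of the coupled rate equations.
#' The favored population receives the input advantage; a trial is correct
#' when it has the highest rate at the end of the trial (ties broken by a
#' seeded coin). All trials are integrated in parallel.
#'
#' @param params a [ratenet_params()].
#' @param duration_s trial duration (default 2 s, a package choice).
#' @param n_trials number of trials (>= 100 recommended).
#' @param dt_ms Euler step in ms.
#' @param seed integer seed.
#' @return list with `accuracy`, `se`, `winners` (per trial), `rates_end`.
#' @export
simulate_ratenet <- function(params, duration_s = 2, n_trials = 200L,
                             dt_ms = 0.1, seed = 1L) {
  n <- params$n
  n_steps <- round(duration_s * 1000 / dt_ms)
  # input split: the favored population gets I + (n-1)/n * dI, others I - dI/n
  Iv <- rep(params$I - params$dI / n, n)
  Iv[params$favored] <- params$I + (n - 1) / n * params$dI
  aE <- dt_ms / params$tau_ms
  aI <- dt_ms / params$tau_i_ms
  nsE <- params$sigma * sqrt(aE)
  nsI <- params$sigma_i_pop * sqrt(aI)
  with_substream(seed, "internal", {
    r <- matrix(0, n_trials, n)
    rI <- numeric(n_trials)
    for (st in seq_len(n_steps)) {
      drive <- params$s * r - params$c_inh * rI +
        matrix(Iv, n_trials, n, byrow = TRUE)
      r_new <- r + aE * (-r + matrix(ratenet_transfer(drive), n_trials, n)) +
        if (nsE > 0) matrix(stats::rnorm(n_trials * n, 0, nsE), n_trials, n) else 0
      rI <- rI + aI * (-rI + ratenet_transfer(params$g / n * rowSums(r))) +
        if (nsI > 0) stats::rnorm(n_trials, 0, nsI) else 0
      r <- r_new
      if (any(!is.finite(r)) || max(r) > 1e6) {
        stop("rate blow-up: reduce the integration step")
      }
    }
    winners <- max.col(r, ties.method = "random")
    acc <- mean(winners == params$favored)
    list(accuracy = acc, se = sqrt(acc * (1 - acc) / n_trials),
         winners = winners, rates_end = r, n_trials = n_trials)
  })
}
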