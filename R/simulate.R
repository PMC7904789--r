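#' Decision bounds
#'
#' @param kind `"none"`, `"absorbing"` (the variable freezes on first touching
#'   `|x| = magnitude`), or `"reflecting"` (the variable is clamped to
#'   `[-magnitude, magnitude]` every step).
#' @param magnitude bound position B > 0 (ignored for `"none"`). The default
#'   B = 1 is a package choice; only the scaling of the noise magnitudes
#'   relative to B matters.
#' @export
bound_spec <- function(kind = c("none", "absorbing", "reflecting"), magnitude = 1) {
  kind <- match.arg(kind)
  if (kind != "none" && magnitude <= 0) stop("bound magnitude must be positive")
  structure(list(kind = kind, magnitude = magnitude), class = "bound_spec")
}

#' Integrator configuration
#'
#' Settings for the Euler-Maruyama integration
#' `x <- x + dt/tau * (-phi'(x)) + sqrt(dt/tau) * (sigma_I xi_I + sigma_S xi_S)`.
#'
#' @param tau integration time constant in seconds (default 0.2).
#' @param dt step in seconds (default `tau/40`; must be `<= tau/10`).
#' @param sigma_i internal-noise magnitude.
#' @param sigma_s stimulus-noise magnitude used in parametric mode (when no
#'   stimulus ensemble is supplied); ignored when frames drive the engine.
#' @param duration_s stimulus duration in seconds (ignored when a stimulus
#'   ensemble supplies its own duration).
#' @param x0 initial condition (default 0).
#' @param seed master seed; internal noise, parametric stimulus noise and
#'   choice tie-breaks are drawn from named substreams of it.
#' @export
integrator_config <- function(tau = 0.2, dt = tau / 40, sigma_i = 0,
                              sigma_s = 0, duration_s = 2, x0 = 0, seed = 1L) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > tau / 10 + 1e-12) stop("dt must be <= tau/10 for a stable Euler scheme")
  if (sigma_i < 0 || sigma_s < 0) stop("noise magnitudes must be non-negative")
  structure(list(tau = tau, dt = dt, sigma_i = sigma_i, sigma_s = sigma_s,
                 duration_s = duration_s, x0 = x0, seed = seed),
            class = "integrator_config")
}

#' Simulate an ensemble of decision trials
#'
#' Euler-Maruyama integration of the diffusion in a potential, for the perfect
#' integrator (flat), the bounded drift-diffusion models (linear + bounds) and
#' the double-well attractor model. The stimulus can be supplied either
#' parametrically (`potential$mu` plus white noise `config$sigma_s`) or as a
#' frame-based [new_stimuli()] ensemble; in the latter case `potential$mu` is
#' ignored and each trial is driven by its own trace (see the coupling note in
#' [new_stimuli()]).
#'
#' For the double-well model the first attractor visited and the number of
#' subsequent transitions are recorded with a hysteresis detector: a trial
#' enters an attractor when `x` crosses the attractor position (`x_C` or
#' `x_E`, computed at zero tilt for stimulus-driven runs), and a switch is
#' counted only when the *opposite* attractor position is subsequently
#' crossed, so noise chatter around the unstable point is not counted.
#'
#' The choice is `sign(x)` at stimulus offset; an exact tie at 0 is broken by
#' a seeded fair coin.
#'
#' @param potential a [potential_spec()].
#' @param config an [integrator_config()].
#' @param stimuli optional [new_stimuli()] ensemble driving the trials.
#' @param bounds a [bound_spec()].
#' @param n_trials number of trials (parametric mode; ignored when `stimuli`
#'   is given).
#' @param record_trajectories if `TRUE`, keep the full `x(t)` matrix
#'   (steps x trials); off by default to bound memory.
#' @param record_transition_times if `TRUE`, keep per-trial signed switch
#'   times (sign = attractor entered).
#' @return object of class `trial_ensemble` with elements `choices` (+/-1),
#'   `x_final`, `first_visit` (+/-1 or NA; double-well only), `n_transitions`,
#'   optional `transition_times`, optional `trajectories`, and metadata.
#' @export
simulate_trials <- function(potential, config, stimuli = NULL,
                            bounds = bound_spec("none"), n_trials = 1000L,
                            record_trajectories = FALSE,
                            record_transition_times = FALSE) {
  tau <- config$tau; dt <- config$dt
  dwell_mode <- potential$family == "double_well"

  if (!is.null(stimuli)) {
    stopifnot(inherits(stimuli, "dwell_stimuli"))
    n_trials <- nrow(stimuli$frames)
    spf <- stimuli$frame_duration / dt
    if (abs(spf - round(spf)) > 1e-8) {
      stop("stimulus frame duration must be an integer multiple of dt")
    }
    spf <- as.integer(round(spf))
    n_steps <- ncol(stimuli$frames) * spf
    duration_s <- n_steps * dt
    white <- stimuli$coupling == "white"
    # per-step coefficient on the fluctuation so the variance integrated over
    # one frame equals that of continuous white noise of the same magnitude
    c_fluct <- if (white) sqrt(stimuli$frame_duration / tau) / spf else dt / tau
    mu_i <- stimuli$mu_per_trial
    fluct <- if (white) stimuli$frames - mu_i else stimuli$frames
  } else {
    n_steps <- as.integer(round(config$duration_s / dt))
    duration_s <- n_steps * dt
    spf <- 1L; white <- TRUE
    mu_i <- rep(potential$mu, n_trials)
    fluct <- NULL
  }

  x <- rep(config$x0, n_trials)
  frozen <- rep(FALSE, n_trials)
  state <- integer(n_trials)        # -1/0/+1 attractor occupancy (double-well)
  first_visit <- rep(NA_real_, n_trials)
  n_trans <- integer(n_trials)
  trans_times <- if (record_transition_times) vector("list", n_trials) else NULL
  traj <- if (record_trajectories) matrix(NA_real_, n_steps, n_trials) else NULL

  if (dwell_mode) {
    att <- fixed_points(potential_spec("double_well", mu = 0, alpha = potential$alpha))
    x_lo <- att[["x_E"]]; x_hi <- att[["x_C"]]
    alpha <- potential$alpha
  }

  # In parametric mode internal and stimulus white noise are combined in one
  # Gaussian draw (statistically identical); stimulus generation proper always
  # lives in its own substream inside the generators.
  sig_step <- if (is.null(stimuli)) {
    sqrt(config$sigma_i^2 + config$sigma_s^2)
  } else {
    config$sigma_i
  }

  dtt <- dt / tau
  sq <- sqrt(dtt)
  B <- bounds$magnitude

  with_substream(config$seed, "internal", {
    for (s in seq_len(n_steps)) {
      f <- ((s - 1L) %/% spf) + 1L
      force_nl <- switch(potential$family,
                         flat = 0,
                         linear = 0,
                         double_well = 2 * alpha * x - 4 * x^3)
      stim_term <- if (is.null(stimuli)) {
        dtt * mu_i
      } else if (white) {
        dtt * mu_i + c_fluct * fluct[, f]
      } else {
        c_fluct * fluct[, f]
      }
      noise <- if (sig_step > 0) sq * sig_step * stats::rnorm(n_trials) else 0
      x_new <- x + dtt * force_nl + stim_term + noise
      if (any(!is.finite(x_new))) {
        stop(sprintf("non-finite decision variable at step %d (trial %d); reduce dt",
                     s, which(!is.finite(x_new))[1]))
      }
      x_new[frozen] <- x[frozen]
      if (bounds$kind == "absorbing") {
        hit <- !frozen & abs(x_new) >= B
        x_new[hit] <- sign(x_new[hit]) * B
        frozen <- frozen | hit
      } else if (bounds$kind == "reflecting") {
        x_new <- pmin(pmax(x_new, -B), B)
      }
      x <- x_new
      if (dwell_mode) {
        up <- x >= x_hi & state != 1L
        dn <- x <= x_lo & state != -1L
        if (any(up)) {
          sw <- up & state == -1L
          n_trans[sw] <- n_trans[sw] + 1L
          nv <- up & state == 0L
          first_visit[nv] <- 1
          if (record_transition_times && any(sw)) {
            for (i in which(sw)) trans_times[[i]] <- c(trans_times[[i]], s * dt)
          }
          state[up] <- 1L
        }
        if (any(dn)) {
          sw <- dn & state == 1L
          n_trans[sw] <- n_trans[sw] + 1L
          nv <- dn & state == 0L
          first_visit[nv] <- -1
          if (record_transition_times && any(sw)) {
            for (i in which(sw)) trans_times[[i]] <- c(trans_times[[i]], -s * dt)
          }
          state[dn] <- -1L
        }
      }
      if (record_trajectories) traj[s, ] <- x
    }
  })

  choices <- sign(x)
  ties <- choices == 0
  if (any(ties)) {
    choices[ties] <- with_substream(config$seed, "tiebreak", {
      sample(c(-1, 1), sum(ties), replace = TRUE)
    })
  }

  structure(list(choices = choices, x_final = x,
                 first_visit = if (dwell_mode) first_visit else rep(NA_real_, n_trials),
                 n_transitions = n_trans,
                 transition_times = trans_times,
                 trajectories = traj,
                 potential = potential, bounds = bounds, config = config,
                 n_trials = n_trials, duration_s = duration_s,
                 stimulus_kind = if (is.null(stimuli)) "parametric" else stimuli$kind),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %s model, %d trials, T = %.3g s\n",
              x$potential$family, x$n_trials, x$duration_s))
  cat(sprintf("  P(choice = +1) = %.3f; transitions/trial = %.3f\n",
              mean(x$choices == 1), mean(x$n_transitions)))
  invisible(x)
}

#' Accuracy surface over stimulus mean, fluctuation magnitude, and duration
#'
#' Runs the simulator over the grid and reports per-cell accuracy (fraction of
#' choices matching `sign(mu)`; cells with `mu = 0` report the probability of
#' a rightward choice) with binomial standard errors.
#'
#' @param potential template [potential_spec()] (its `mu` is replaced cell by
#'   cell).
#' @param bounds a [bound_spec()].
#' @param mu_grid,sigma_s_grid,T_grid grids of stimulus mean, fluctuation
#'   magnitude and duration (seconds).
#' @param n_trials trials per cell (>= 100).
#' @param config base [integrator_config()]; its `sigma_s`, `duration_s` are
#'   replaced cell by cell.
#' @param seed master seed; each cell gets its own substream.
#' @return data.frame with columns `mu`, `sigma_s`, `T`, `accuracy`, `se`, `n`.
#' @export
run_psychometric <- function(potential, bounds = bound_spec("none"),
                             mu_grid = 0.15, sigma_s_grid, T_grid = 2,
                             n_trials = 1000L, config = integrator_config(),
                             seed = 1L) {
  if (n_trials < 100) stop("n_trials must be >= 100 per cell")
  grid <- expand.grid(mu = mu_grid, sigma_s = sigma_s_grid, T = T_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- se <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pot <- potential
    pot$mu <- grid$mu[i]
    cfg <- config
    cfg$sigma_s <- grid$sigma_s[i]
    cfg$duration_s <- grid$T[i]
    cfg$seed <- substream_seed(seed, "cell", i)
    ens <- simulate_trials(pot, cfg, bounds = bounds, n_trials = n_trials)
    p <- if (grid$mu[i] == 0) mean(ens$choices == 1) else
      mean(ens$choices == sign(grid$mu[i]))
    acc[i] <- p
    se[i] <- sqrt(p * (1 - p) / n_trials)
  }
  grid$accuracy <- acc
  grid$se <- se
  grid$n <- n_trials
  grid
}
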