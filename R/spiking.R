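#' Parameters of the spiking winner-take-all network
#'
#' A current-based leaky integrate-and-fire network with two selective
#' excitatory populations (A, B) and one shared inhibitory population, sparse
#' random connectivity (pairwise probability `eps`), exponential synapses with
#' a fixed delay, instantaneous external Poisson synapses, and a common
#' stimulus current per excitatory population (mean `I0 * (1 +/- mu)`, OU
#' fluctuations of magnitude `sigma_s`, correlation time 20 ms).
#'
#' The reference population sizes are 1000 excitatory per selective population
#' and 500 inhibitory; `scale` divides the sizes and multiplies the recurrent
#' weights by the same factor, preserving the mean recurrent drive (the
#' package default `scale = 5` gives the reduced 200/100 network used in
#' tests). The weights, delays and external drive are package-chosen by a
#' tuning procedure documented in the methods vignette: the symmetric low-rate
#' state must be stable without stimulus, and with a transient kick one
#' population must persist at a high rate (winner-take-all bistability); see
#' [check_attractor_persistence()].
#'
#' @param scale population down-scaling factor (1 = reference size).
#' @param eps connection probability.
#' @param J_EE,J_IE,J_EI synaptic weights (mV, at reference scale).
#' @param delay_ms synaptic transmission delay.
#' @param tau_m_e_ms,tau_m_i_ms membrane time constants.
#' @param tau_s_e_ms,tau_s_i_ms synaptic time constants.
#' @param E_l_mV,theta_mV,E_r_mV rest, threshold, reset (mV).
#' @param tau_ref_ms absolute refractory period.
#' @param nu_ext_e_hz,nu_ext_i_hz external Poisson rates per neuron.
#' @param J_ext_e_mV,J_ext_i_mV external synaptic jumps.
#' @param I0_pA baseline stimulus current; `g_L_nS` converts pA to mV.
#' @param tau_stim_ms stimulus OU correlation time.
#' @export
network_params <- function(scale = 5, eps = 0.1,
                           J_EE = 0.17, J_IE = 0.2, J_EI = 1.1,
                           delay_ms = 0.5,
                           tau_m_e_ms = 20, tau_m_i_ms = 10,
                           tau_s_e_ms = 20, tau_s_i_ms = 5,
                           E_l_mV = 0, theta_mV = 20, E_r_mV = 10,
                           tau_ref_ms = 2,
                           nu_ext_e_hz = 6800, nu_ext_i_hz = 8400,
                           J_ext_e_mV = 0.1, J_ext_i_mV = 0.1,
                           I0_pA = 50, g_L_nS = 10, tau_stim_ms = 20) {
  if (eps < 0 || eps > 1) stop("connection probability must be in [0, 1]")
  if (theta_mV <= E_r_mV) stop("threshold must exceed reset")
  structure(list(n_e = as.integer(round(1000 / scale)),
                 n_i = as.integer(round(500 / scale)),
                 scale = scale, eps = eps,
                 J_EE = J_EE * scale, J_IE = J_IE * scale, J_EI = J_EI * scale,
                 delay_ms = delay_ms,
                 tau_m_e_ms = tau_m_e_ms, tau_m_i_ms = tau_m_i_ms,
                 tau_s_e_ms = tau_s_e_ms, tau_s_i_ms = tau_s_i_ms,
                 E_l_mV = E_l_mV, theta_mV = theta_mV, E_r_mV = E_r_mV,
                 tau_ref_ms = tau_ref_ms,
                 nu_ext_e_hz = nu_ext_e_hz, nu_ext_i_hz = nu_ext_i_hz,
                 J_ext_e_mV = J_ext_e_mV, J_ext_i_mV = J_ext_i_mV,
                 I0_pA = I0_pA, g_L_nS = g_L_nS, tau_stim_ms = tau_stim_ms),
            class = "network_params")
}

#' Build a network instance (fixed random connectivity)
#'
#' Samples the sparse adjacency (probability `eps` per ordered pair, no
#' self-connections within a population block) from the connectivity
#' substream of `seed` and returns it in compressed form for the simulator.
#' Two builds with the same seed are identical.
#'
#' @param params a [network_params()].
#' @param seed integer seed.
#' @return object of class `lif_network`.
#' @export
build_network <- function(params, seed = 1L) {
  n_e <- params$n_e; n_i <- params$n_i
  N <- 2L * n_e + n_i
  blocks <- list(
    # list(pre range, post range, weight sign/type)
    list(pre = 1:n_e, post = 1:n_e, w = params$J_EE, self = TRUE),           # A->A
    list(pre = n_e + 1:n_e, post = n_e + 1:n_e, w = params$J_EE, self = TRUE), # B->B
    list(pre = 1:n_e, post = 2L * n_e + 1:n_i, w = params$J_IE, self = FALSE), # A->I
    list(pre = n_e + 1:n_e, post = 2L * n_e + 1:n_i, w = params$J_IE, self = FALSE), # B->I
    list(pre = 2L * n_e + 1:n_i, post = 1:n_e, w = -params$J_EI, self = FALSE), # I->A
    list(pre = 2L * n_e + 1:n_i, post = n_e + 1:n_e, w = -params$J_EI, self = FALSE), # I->B
    list(pre = 2L * n_e + 1:n_i, post = 2L * n_e + 1:n_i, w = 0, self = TRUE))  # I->I (absent)
  pre_all <- integer(0); post_all <- integer(0); w_all <- numeric(0)
  with_substream(seed, "connectivity", {
    for (b in blocks) {
      if (b$w == 0) next
      m <- matrix(stats::runif(length(b$pre) * length(b$post)) < params$eps,
                  length(b$pre), length(b$post))
      if (b$self) diag(m) <- FALSE
      idx <- which(m, arr.ind = TRUE)
      pre_all <- c(pre_all, b$pre[idx[, 1]])
      post_all <- c(post_all, b$post[idx[, 2]])
      w_all <- c(w_all, rep(b$w, nrow(idx)))
    }
  })
  o <- order(pre_all)
  pre_all <- pre_all[o]; post_all <- post_all[o]; w_all <- w_all[o]
  ptr <- c(0L, cumsum(tabulate(pre_all, nbins = N)))
  net <- c(params, list(adj_ptr = as.integer(ptr),
                        adj_idx = as.integer(post_all - 1L),
                        adj_w = w_all, seed = seed))
  class(net) <- "lif_network"
  net
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf("<lif_network> 2 x %d excitatory + %d inhibitory neurons, %d synapses\n",
              x$n_e, x$n_i, length(x$adj_idx)))
  invisible(x)
}

#' Run one trial of the spiking network
#'
#' A 500 ms stimulus-free interval precedes stimulus onset (transients from
#' the random initial conditions die out); the stimulus currents are then
#' injected for `duration_s`. The choice is the population with more spikes
#' over the last 100 ms of the stimulus period (tie broken by a seeded coin);
#' a trial with no excitatory spikes in the readout window is flagged
#' undecided.
#'
#' @param network a [build_network()] object.
#' @param stimulus output of [ou_currents()] covering `duration_s`, or NULL
#'   for no stimulus drive.
#' @param duration_s stimulus duration (seconds).
#' @param pre_window_s pre-stimulus interval (default 0.5 s).
#' @param dt_ms Euler step (default 0.1 ms).
#' @param seed integer seed (initial conditions + external input substream).
#' @param kick_pA,kick_window_s optional extra current to population A during
#'   a window after stimulus onset (attractor persistence checks).
#' @param record_raster keep the spike raster (time_ms, neuron id).
#' @return object of class `network_trial` with `choice` (+1 = A), `rates`
#'   (30 ms-window population rates in Hz), `undecided`, and counts.
#' @export
run_trial <- function(network, stimulus = NULL, duration_s = 1,
                      pre_window_s = 0.5, dt_ms = 0.1, seed = 1L,
                      kick_pA = 0, kick_window_s = c(0, 0),
                      record_raster = FALSE) {
  if (duration_s + pre_window_s < 0.5) stop("total simulated time must be >= 0.5 s")
  n_steps <- as.integer(round((pre_window_s + duration_s) * 1000 / dt_ms))
  stim_on <- as.integer(round(pre_window_s * 1000 / dt_ms))
  n_stim <- n_steps - stim_on
  if (is.null(stimulus)) {
    sA <- sB <- rep(network$I0_pA, n_stim)
  } else {
    if (length(stimulus$I_A) < n_stim) stop("stimulus shorter than the trial")
    sA <- stimulus$I_A[seq_len(n_stim)]; sB <- stimulus$I_B[seq_len(n_stim)]
  }
  res <- with_substream(seed, "internal", {
    lif_trial_cpp(unclass(network), sA, sB, dt_ms, n_steps, stim_on,
                  30, kick_pA,
                  stim_on + as.integer(round(kick_window_s[1] * 1000 / dt_ms)),
                  stim_on + as.integer(round(kick_window_s[2] * 1000 / dt_ms)),
                  record_raster)
  })
  # drop a trailing partial count window
  nb <- (n_steps * dt_ms) %/% res$bin_ms
  res$count_A <- res$count_A[seq_len(nb)]
  res$count_B <- res$count_B[seq_len(nb)]
  res$count_I <- res$count_I[seq_len(nb)]
  undecided <- (res$last100_A + res$last100_B) == 0
  choice <- if (res$last100_A != res$last100_B) {
    if (res$last100_A > res$last100_B) 1 else -1
  } else {
    with_substream(seed, "tiebreak", sample(c(-1, 1), 1L))
  }
  to_hz <- function(cnt) cnt / network$n_e / (res$bin_ms / 1000)
  structure(list(choice = choice, undecided = undecided,
                 rate_A = to_hz(res$count_A), rate_B = to_hz(res$count_B),
                 rate_I = res$count_I / network$n_i / 0.03,
                 bin_ms = res$bin_ms, last100 = c(A = res$last100_A, B = res$last100_B),
                 raster = if (record_raster)
                   data.frame(time_s = res$raster_t_ms / 1000, neuron_id = res$raster_id)
                 else NULL,
                 stim_on_s = pre_window_s, duration_s = duration_s),
            class = "network_trial")
}

#' @export
print.network_trial <- function(x, ...) {
  cat(sprintf("<network_trial> choice = %+d%s; late rates A/B = %.1f/%.1f Hz\n",
              x$choice, if (x$undecided) " (undecided)" else "",
              utils::tail(x$rate_A, 1), utils::tail(x$rate_B, 1)))
  invisible(x)
}

#' Winner-take-all bistability self-check
#'
#' Verifies the defining properties of the tuned operating point: (a)
#' without any stimulus drive the symmetric low-rate state is stable (both
#' populations below `low_hz` after 1.5 s); (b) with the baseline current on
#' and a strong transient kick to population A, A persists at a high rate
#' (> `high_hz`) at least 1 s after kick offset while B stays low
#' (winner-take-all attractors). With the baseline current on the symmetric
#' state itself is unstable -- that is the decision-forming regime near the
#' bifurcation, not a defect.
#'
#' @param params a [network_params()].
#' @param seed integer seed.
#' @param low_hz,high_hz rate criteria (defaults 10 and 20 Hz).
#' @return logical; attributes carry the measured rates.
#' @export
check_attractor_persistence <- function(params, seed = 1L, low_hz = 10,
                                        high_hz = 20) {
  net <- build_network(params, seed = seed)
  late <- function(r) mean(utils::tail(r, 10))
  off <- ou_currents(0, 0, duration_s = 1.5, I0 = 0,
                     seed = substream_seed(seed, "off"))
  quiet <- run_trial(net, off, duration_s = 1.5, seed = substream_seed(seed, "quiet"))
  ok_low <- late(quiet$rate_A) < low_hz && late(quiet$rate_B) < low_hz
  kicked <- run_trial(net, NULL, duration_s = 2.0,
                      seed = substream_seed(seed, "kick"),
                      kick_pA = 200, kick_window_s = c(0, 0.4))
  ok_high <- late(kicked$rate_A) > high_hz && late(kicked$rate_B) < low_hz
  structure(ok_low && ok_high,
            quiet_rates = c(A = late(quiet$rate_A), B = late(quiet$rate_B)),
            kicked_rates = c(A = late(kicked$rate_A), B = late(kicked$rate_B)))
}

#' Accuracy surface and psychophysical kernels of the spiking network
#'
#' For each (sigma_S, T) cell, runs `n_trials` trials with fresh connectivity,
#' initial conditions, external inputs and stimulus realizations, records the
#' choice, and computes the psychophysical kernel from the difference of the
#' injected stimulus currents binned at 100 ms.
#'
#' @param params a [network_params()].
#' @param mu mean stimulus-difference fraction (> 0: A is correct).
#' @param sigma_s_grid_pA stimulus-fluctuation magnitudes (pA).
#' @param T_grid_s stimulus durations (seconds).
#' @param n_trials trials per cell.
#' @param seed master seed.
#' @param fresh_connectivity resample the adjacency every trial (default), as
#'   in ensemble averaging over network realizations.
#' @return list with `cells` (data.frame sigma_s, T, accuracy, se, n_undecided)
#'   and `kernels` (one `pk_kernel` per cell).
#' @export
run_spiking_experiment <- function(params, mu = 0.05, sigma_s_grid_pA,
                                   T_grid_s, n_trials = 200L, seed = 1L,
                                   fresh_connectivity = TRUE) {
  if (n_trials < 50) stop("need at least 50 trials per cell")
  grid <- expand.grid(sigma_s = sigma_s_grid_pA, T = T_grid_s,
                      KEEP.OUT.ATTRS = FALSE)
  kernels <- vector("list", nrow(grid))
  grid$accuracy <- grid$se <- NA_real_
  grid$n_undecided <- 0L
  net0 <- build_network(params, seed = substream_seed(seed, "connectivity"))
  for (g in seq_len(nrow(grid))) {
    Tcell <- grid$T[g]
    nb <- as.integer(round(Tcell / 0.1))
    diffs <- matrix(NA_real_, n_trials, nb)
    choices <- numeric(n_trials)
    und <- 0L
    for (tr in seq_len(n_trials)) {
      cseed <- substream_seed(seed, sprintf("cell%d-trial", g), tr)
      net <- if (fresh_connectivity) build_network(params, seed = cseed) else net0
      st <- ou_currents(mu, grid$sigma_s[g], params$tau_stim_ms, Tcell,
                        dt_ms = 0.1, I0 = params$I0_pA,
                        seed = substream_seed(cseed, "stim"))
      trl <- run_trial(net, st, duration_s = Tcell,
                       seed = substream_seed(cseed, "run"))
      choices[tr] <- trl$choice
      if (trl$undecided) und <- und + 1L
      d <- st$I_A - st$I_B
      per_bin <- length(d) %/% nb
      diffs[tr, ] <- colMeans(matrix(d[seq_len(nb * per_bin)], per_bin, nb))
    }
    p <- mean(choices == 1)
    grid$accuracy[g] <- p
    grid$se[g] <- sqrt(p * (1 - p) / n_trials)
    grid$n_undecided[g] <- und
    stim_obj <- new_stimuli(diffs, 0.1, rep(2 * params$I0_pA * mu, n_trials),
                            grid$sigma_s[g], "ou_current")
    kernels[g] <- list(tryCatch(compute_pk(stim_obj, choices),
                                error = function(e) NULL))
  }
  list(cells = grid, kernels = kernels)
}
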