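#' Read and validate an experiment configuration
#'
#' Configurations are YAML (or equivalent R lists) with a `task` field naming
#' the analysis, a `seed`, an `out_dir`, and task-specific parameter blocks.
#' Unknown keys are an error (named in the message), so typos cannot silently
#' fall back to defaults.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  tasks <- names(pipeline_schemas())
  if (is.null(config$task) || !config$task %in% tasks) {
    stop("config$task must be one of: ", paste(tasks, collapse = ", "))
  }
  allowed <- c("task", "seed", "out_dir", pipeline_schemas()[[config$task]])
  bad <- setdiff(names(config), allowed)
  if (length(bad)) {
    stop("unknown config key(s) for task '", config$task, "': ",
         paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "."
  config
}

pipeline_schemas <- function() {
  list(
    simulate = c("model", "mu", "sigma_s", "sigma_i", "T", "trials", "alpha",
                 "bound", "tau"),
    pk = c("model", "mu", "sigma_s", "sigma_i", "T", "trials", "alpha",
           "bound", "tau", "n_boot"),
    theory = c("alpha", "mu", "sigma", "T_over_tau", "tau"),
    consistency = c("alpha", "sigma_i", "sigma_s_grid", "n_stimuli",
                    "n_passes", "T", "tau"),
    fit_pulses = c("table_csv", "n_restarts"),
    spiking = c("mu", "sigma_s_grid", "T_grid", "trials", "scale"),
    rate_net = c("n_choices", "sigma_grid", "trials", "duration_s"),
    reproduce = c("analysis", "scale"))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2^28
  sprintf("%07x", h)
}

write_table_with_header <- function(df, path, units, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s; config: %s", units, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

model_potential <- function(model, mu, alpha) {
  switch(model,
         pi = list(pot = potential_spec("flat", mu = mu), bnd = bound_spec("none")),
         ddma = list(pot = potential_spec("linear", mu = mu),
                     bnd = bound_spec("absorbing", 1)),
         ddmr = list(pot = potential_spec("linear", mu = mu),
                     bnd = bound_spec("reflecting", 1)),
         dwm = list(pot = potential_spec("double_well", mu = mu, alpha = alpha),
                    bnd = bound_spec("none")),
         stop("unknown model tag: ", model))
}

#' Run a configured analysis pipeline
#'
#' Dispatches a validated configuration to the corresponding analysis, writes
#' CSV/JSON artifacts plus the resolved configuration and a run log into
#' `out_dir`, and returns the paths. Outputs are deterministic for a fixed
#' seed (only the log carries timestamps). Every table carries a header line
#' naming units and the configuration hash.
#'
#' @param config path to YAML or a named list (see [read_config()]).
#' @return invisible character vector of file paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  paths <- character(0)
  p <- function(f) file.path(cfg$out_dir, f)
  gv <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]

  if (cfg$task == "simulate") {
    mp <- model_potential(gv("model", "dwm"), gv("mu", 0.15), gv("alpha", 1))
    cfgI <- integrator_config(tau = gv("tau", 0.2), sigma_i = gv("sigma_i", 0.1),
                              sigma_s = gv("sigma_s", 0.3),
                              duration_s = gv("T", 2), seed = cfg$seed)
    ens <- simulate_trials(mp$pot, cfgI, bounds = mp$bnd,
                           n_trials = gv("trials", 1000L))
    df <- data.frame(trial = seq_len(ens$n_trials), choice = ens$choices,
                     x_final = ens$x_final, first_visit = ens$first_visit,
                     n_transitions = ens$n_transitions)
    paths <- c(paths, write_table_with_header(df, p("results.csv"),
                                              "choice/first_visit: sign; x: evidence units", hash))
  } else if (cfg$task == "pk") {
    mp <- model_potential(gv("model", "dwm"), 0, gv("alpha", 1))
    tau <- gv("tau", 0.2)
    cfgI <- integrator_config(tau = tau, sigma_i = gv("sigma_i", 0.1),
                              duration_s = gv("T", 2), seed = cfg$seed)
    n_frames <- as.integer(round(cfgI$duration_s / cfgI$dt))
    st <- gaussian_frames(gv("trials", 2000L), n_frames, gv("mu", 0),
                          gv("sigma_s", 0.3),
                          seed = substream_seed(cfg$seed, "stimulus"),
                          frame_duration = cfgI$dt)
    ens <- simulate_trials(mp$pot, cfgI, stimuli = st, bounds = mp$bnd)
    pk <- bootstrap_pk(st, ens$choices, n_boot = gv("n_boot", 1000L),
                       seed = cfg$seed, bin_s = tau / 10)
    df <- data.frame(time_s = pk$times, pk = pk$pk, sem = pk$sem)
    paths <- c(paths, write_table_with_header(df, p("pk.csv"),
                                              "time_s: s; pk: AUROC", hash))
  } else if (cfg$task == "theory") {
    pot <- potential_spec("double_well", mu = gv("mu", 0.15),
                          alpha = gv("alpha", 1))
    kp <- kramers_accuracy(pot, gv("sigma", 0.4), gv("T_over_tau", 10))
    out <- kp[c("p0", "k_c", "k_e", "p_c", "p_e", "p_inf", "accuracy")]
    out$fixed_points <- as.list(kp$fixed_points)
    jsonlite::write_json(out, p("prediction.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p("prediction.json"))
  } else if (cfg$task == "consistency") {
    pot <- potential_spec("double_well", mu = 0, alpha = gv("alpha", 1))
    cfgI <- integrator_config(tau = gv("tau", 0.2), sigma_i = gv("sigma_i", 0.1),
                              duration_s = gv("T", 2), seed = cfg$seed)
    cr <- double_pass(pot, cfgI, gv("sigma_s_grid", seq(0.1, 1.1, 0.2)),
                      n_stimuli = gv("n_stimuli", 100L),
                      n_passes = gv("n_passes", 20L), seed = cfg$seed)
    df <- data.frame(sigma_s = cr$sigma_s_grid, consistency = cr$consistency,
                     se = cr$se)
    paths <- c(paths, write_table_with_header(df, p("consistency.csv"),
                                              "sigma_s: evidence units", hash))
  } else if (cfg$task == "fit_pulses") {
    tab <- utils::read.csv(cfg$table_csv, comment.char = "#")
    fit <- dwm_fit(tab, n_restarts = gv("n_restarts", 10L), seed = cfg$seed)
    out <- list(coefficients = as.list(fit$coefficients),
                ci95 = as.data.frame(fit$ci95), loglik = fit$loglik,
                sigma_i_max = fit$sigma_i_max, predicted = fit$table)
    jsonlite::write_json(out, p("fit.json"), auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- c(paths, p("fit.json"))
  } else if (cfg$task == "spiking") {
    ex <- run_spiking_experiment(network_params(scale = gv("scale", 5)),
                                 mu = gv("mu", 0.05),
                                 sigma_s_grid_pA = gv("sigma_s_grid", c(5, 20, 60)),
                                 T_grid_s = gv("T_grid", 1),
                                 n_trials = gv("trials", 100L), seed = cfg$seed)
    paths <- c(paths, write_table_with_header(ex$cells, p("spiking_accuracy.csv"),
                                              "sigma_s: pA; T: s", hash))
  } else if (cfg$task == "rate_net") {
    grid <- gv("sigma_grid", c(0.06, 0.18, 0.5))
    acc <- vapply(seq_along(grid), function(i) {
      simulate_ratenet(ratenet_params(gv("n_choices", 3L), sigma = grid[i]),
                       duration_s = gv("duration_s", 2),
                       n_trials = gv("trials", 200L),
                       seed = substream_seed(cfg$seed, "ratenet", i))$accuracy
    }, numeric(1))
    df <- data.frame(sigma = grid, accuracy = acc)
    paths <- c(paths, write_table_with_header(df, p("acc.csv"),
                                              "sigma: rate units", hash))
  } else if (cfg$task == "reproduce") {
    paths <- c(paths, reproduce(gv("analysis", "psychometric"), cfg$out_dir,
                                seed = cfg$seed, scale = gv("scale", 1)))
  }

  yaml::write_yaml(cfg, p("config_resolved.yaml"))
  writeLines(c(sprintf("dwell %s", as.character(utils::packageVersion("dwell"))),
               sprintf("task: %s; seed: %d; config hash: %s", cfg$task,
                       as.integer(cfg$seed), hash),
               sprintf("elapsed: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))),
             p("run_log.txt"))
  invisible(c(paths, p("config_resolved.yaml"), p("run_log.txt")))
}

#' Regenerate desk-scale versions of the package's headline analyses
#'
#' Each analysis tag runs a reduced-size version of the corresponding
#' pipeline and writes its tables: `kernels-canonical` canonical-model
#' kernels across fluctuation magnitudes; `kernel-sweep` attractor-model
#' kernel area/slope sweep; `psychometric` accuracy versus fluctuations with
#' the analytic overlay; `consistency` double-pass consistency and the
#' transition diagnostic; `brightness-duration` brightness-stimulus kernel
#' slopes across durations; `two-pulse-fit` a synthetic two-pulse fit with
#' delay-robustness curves.
#'
#' @param analysis one of `"kernels-canonical"`, `"kernel-sweep"`,
#'   `"psychometric"`, `"consistency"`, `"brightness-duration"`,
#'   `"two-pulse-fit"`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param scale trial-count multiplier (1 = desk scale).
#' @return character vector of files written.
#' @export
reproduce <- function(analysis = c("kernels-canonical", "kernel-sweep",
                                   "psychometric", "consistency",
                                   "brightness-duration", "two-pulse-fit"),
                      out_dir = ".", seed = 1L, scale = 1) {
  analysis <- match.arg(analysis)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(list(analysis = analysis, seed = seed, scale = scale))
  p <- function(f) file.path(out_dir, f)
  tau <- 0.2
  n <- function(base) as.integer(ceiling(base * scale))

  if (analysis == "kernels-canonical") {
    grid <- expand.grid(model = c("pi", "ddma", "ddmr"),
                        sigma_s = c(0.03, 0.28, 0.69), stringsAsFactors = FALSE)
    grid$slope <- NA_real_
    rows <- list()
    for (i in seq_len(nrow(grid))) {
      mp <- model_potential(grid$model[i], 0, 1)
      cfgI <- integrator_config(tau = tau, sigma_i = 0.1, duration_s = 2,
                                seed = substream_seed(seed, "kc", i))
      st <- gaussian_frames(n(2000), 400L, 0, grid$sigma_s[i],
                            seed = substream_seed(seed, "kc-stim", i),
                            frame_duration = cfgI$dt)
      ens <- simulate_trials(mp$pot, cfgI, stimuli = st, bounds = mp$bnd)
      pk <- compute_pk(st, ens$choices, bin_s = tau / 2)
      grid$slope[i] <- pk_slope(pk)
      rows[[i]] <- data.frame(model = grid$model[i], sigma_s = grid$sigma_s[i],
                              time_s = pk$times, pk = pk$pk)
    }
    f1 <- write_table_with_header(do.call(rbind, rows), p("kernels_canonical_pk.csv"),
                                  "pk: AUROC", hash)
    f2 <- write_table_with_header(grid, p("kernels_canonical_slopes.csv"),
                                  "slope: normalized (-1, 1)", hash)
    return(c(f1, f2))
  }

  if (analysis == "kernel-sweep") {
    sw <- pk_regime_sweep(alpha = 1, sigma_s_grid = seq(0.2, 1, by = 0.2),
                          sigma_i = 0.1, T = 2, n_trials = n(2000), seed = seed)
    return(write_table_with_header(sw, p("kernel_sweep.csv"),
                                   "slope: (-1,1); npka: fraction", hash))
  }

  if (analysis == "psychometric") {
    pot <- potential_spec("double_well", mu = 0.15, alpha = 1)
    sg <- seq(0.15, 0.9, by = 0.15)
    sim <- run_psychometric(pot, mu_grid = 0.15, sigma_s_grid = sg, T_grid = 2,
                            n_trials = n(2000),
                            config = integrator_config(tau = tau, sigma_i = 0),
                            seed = seed)
    sim$theory <- vapply(sg, function(s)
      kramers_accuracy(pot, s, 10)$accuracy, numeric(1))
    return(write_table_with_header(sim, p("psychometric_accuracy.csv"),
                                   "accuracy: probability", hash))
  }

  if (analysis == "consistency") {
    pot <- potential_spec("double_well", mu = 0, alpha = 1)
    cfgI <- integrator_config(tau = tau, sigma_i = 0.1, duration_s = 2, seed = seed)
    sg <- seq(0.1, 1.1, by = 0.2)
    cr <- double_pass(pot, cfgI, sg, n_stimuli = n(100), n_passes = 20, seed = seed)
    dg <- transition_diag(pot, cfgI, sg, sigma_i = 0.1, n_trials = n(1000),
                          seed = substream_seed(seed, "diag"))
    df <- data.frame(sigma_s = sg, consistency = cr$consistency, se = cr$se,
                     delta_p = dg$delta)
    return(write_table_with_header(df, p("consistency.csv"),
                                   "consistency, delta_p: probability", hash))
  }

  if (analysis == "brightness-duration") {
    sl <- brightness_slope_sweep(durations_s = c(1, 2, 3, 5), n_trials = n(2000),
                                 seed = seed)
    return(write_table_with_header(sl, p("brightness_slopes.csv"),
                                   "slope: normalized (-1, 1)", hash))
  }

  # two-pulse-fit
  truth <- c(k = 0.012, alpha = 0.70, sigma = 0.52, tau = 3.3)
  tab <- simulate_condition_table(truth,
                                  design = two_pulse_design(n_per_condition = n(2000)),
                                  seed = substream_seed(seed, "table"))
  fit <- dwm_fit(tab, n_restarts = 6L, seed = seed)
  dr <- delay_robustness(coef(fit))
  f1 <- write_table_with_header(fit$table, p("two_pulse_fit.csv"),
                                "accuracy: probability", hash)
  f2 <- write_table_with_header(dr$curves, p("two_pulse_delay.csv"),
                                "accuracy: probability; delay_s: s", hash)
  jsonlite::write_json(list(coefficients = as.list(coef(fit)),
                            sigma_i_max = dr$sigma_i_max),
                       p("two_pulse_params.json"), auto_unbox = TRUE, digits = NA)
  c(f1, f2, p("two_pulse_params.json"))
}

#' Attractor-model kernel area and slope across a fluctuation sweep
#'
#' Helper used by the regime analyses: simulates the double-well model on
#' Gaussian frame stimuli over a grid of fluctuation magnitudes and returns
#' the normalized kernel slope and area (the latter relative to the
#' ideal-observer kernel on the same stimuli).
#'
#' @param alpha barrier parameter.
#' @param sigma_s_grid fluctuation magnitudes.
#' @param sigma_i internal noise.
#' @param T stimulus duration (s).
#' @param tau integrator time constant (s).
#' @param n_trials trials per grid point.
#' @param seed master seed.
#' @return data.frame with `sigma_s`, `slope`, `npka`.
#' @export
pk_regime_sweep <- function(alpha = 1, sigma_s_grid, sigma_i = 0.1, T = 2,
                            tau = 0.2, n_trials = 2000L, seed = 1L) {
  out <- data.frame(sigma_s = sigma_s_grid, slope = NA_real_, npka = NA_real_)
  pot <- potential_spec("double_well", mu = 0, alpha = alpha)
  cfg <- integrator_config(tau = tau, sigma_i = sigma_i, duration_s = T)
  n_frames <- as.integer(round(T / cfg$dt))
  for (i in seq_along(sigma_s_grid)) {
    st <- gaussian_frames(n_trials, n_frames, 0, sigma_s_grid[i],
                          seed = substream_seed(seed, "sweep-stim", i),
                          frame_duration = cfg$dt)
    cfg$seed <- substream_seed(seed, "sweep-run", i)
    ens <- simulate_trials(pot, cfg, stimuli = st)
    pk <- compute_pk(st, ens$choices, bin_s = tau / 2)
    # ideal observer: perfect integration of the same stimuli, no internal noise
    ideal_choice <- sign(rowSums(st$frames - st$mu_per_trial))
    ref <- compute_pk(st, ideal_choice, bin_s = tau / 2)
    out$slope[i] <- pk_slope(pk)
    out$npka[i] <- npka(pk, ref)
  }
  out
}

#' Kernel slopes of the attractor model on brightness-disc stimuli
#'
#' Fixed model parameters across stimulus durations: the hallmark crossover
#' from primacy (negative slope, short trials) to recency (positive slope,
#' long trials) with no parameter change. The frame-wise net brightness
#' difference drives the model drift directly and the engine's own stimulus
#' noise is zero.
#'
#' @param durations_s stimulus durations (multiples of 0.5 s).
#' @param alpha,sigma_i,tau model parameters (defaults 0.8, 0.3, 0.2 s).
#' @param n_trials trials per duration.
#' @param seed master seed.
#' @param ... forwarded to [brightness_disc_frames()].
#' @return data.frame with `T`, `slope`, `accuracy`.
#' @export
brightness_slope_sweep <- function(durations_s = c(1, 2, 3, 5), alpha = 0.8,
                                   sigma_i = 0.3, tau = 0.2,
                                   n_trials = 2000L, seed = 1L, ...) {
  out <- data.frame(T = durations_s, slope = NA_real_, accuracy = NA_real_)
  pot <- potential_spec("double_well", mu = 0, alpha = alpha)
  for (i in seq_along(durations_s)) {
    st <- brightness_disc_frames(n_trials, durations_s[i],
                                 seed = substream_seed(seed, "bright", i), ...)
    cfg <- integrator_config(tau = tau, sigma_i = sigma_i,
                             duration_s = durations_s[i],
                             seed = substream_seed(seed, "bright-run", i))
    ens <- simulate_trials(pot, cfg, stimuli = st)
    pk <- compute_pk(st, ens$choices)
    out$slope[i] <- pk_slope(pk)
    out$accuracy[i] <- mean(ens$choices == sign(st$mu_per_trial))
  }
  out
}

#' Read a two-pulse condition table from CSV
#'
#' Columns `coh1`, `coh2` (empty/NA for single pulse), `delay_ms`, `n_trials`,
#' `n_correct`; lines starting with `#` are ignored.
#'
#' @param path CSV path.
#' @export
read_condition_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("coh1", "coh2", "n_trials", "n_correct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("condition table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
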