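# dwell

Double-well attractor models of perceptual evidence integration.

## What this package is for

In fixed-duration discrimination tasks, a decision variable `x(t)` integrates
the momentary sensory evidence `S(t) = μ + σ_S ξ_S(t)` plus internal noise:

    τ dx/dt = −φ'(x) + σ_S ξ_S(t) + σ_I ξ_I(t),     choice = sign(x(T))

The potential `φ(x)` encodes the integration rule. The canonical models — the
perfect integrator (`φ = 0`), and drift-diffusion with absorbing or
reflecting bounds (`φ = −μx`) — each have a fixed temporal weighting profile
(flat, primacy, recency). The double-well model,

    φ(x) = −μx − αx² + x⁴,

the one-dimensional reduction of a winner-take-all attractor network, instead
*crosses over* between regimes as the stimulus fluctuation magnitude `σ_S` or
duration `T` grows. Because escaping the error attractor is exponentially
easier than escaping the correct one (Kramers rates with barrier difference
`∝ μ`), there is a regime where stimulus noise corrects more mistakes than it
creates: accuracy depends non-monotonically on `σ_S`, double-pass choice
consistency dips where internal and stimulus noise must cooperate to cause
transitions, and a categorical decision survives a working-memory delay that
degrades an analog (perfect-integrator) memory.

The package provides, for researchers in perceptual decision making:

* a seeded Euler–Maruyama engine covering all four models, with
  first-visit/transition bookkeeping (`simulate_trials()`,
  `run_psychometric()`);
* psychophysical-kernel reverse correlation by time-resolved ROC analysis,
  with normalized area and slope indices and bootstrap errors
  (`compute_pk()`, `npka()`, `pk_slope()`, `bootstrap_pk()`);
* the full Kramers-rate accuracy theory of the double-well model
  (`kramers_accuracy()`, `first_visit_probability()`, `transition_rates()`,
  `delay_noise_bound()`);
* double-pass consistency with an unbiased pass-pair estimator
  (`double_pass()`, `transition_diag()`);
* the central estimator `dwm_fit()`: maximum-likelihood fitting of
  `(k, α, σ, τ)` to two-pulse accuracy tables, with Hessian confidence
  intervals, a primacy–recency index (`pri()`), and delay-robustness
  analysis (`delay_robustness()`) — plus `print`, `summary`, `coef`,
  `confint`, `predict`, `simulate`, `residuals` and `plot` methods;
* synthetic-stimulus generators for every design the analyses consume
  (`gaussian_frames()`, `zero_integral_frames()`, `brightness_disc_frames()`,
  `two_pulse_design()`, `ou_currents()`);
* a reduced-scale spiking winner-take-all network (`build_network()`,
  `run_trial()`, `run_spiking_experiment()`) and an n-choice rate network
  (`simulate_ratenet()`);
* a config-driven pipeline runner and desk-scale regeneration drivers
  (`run_pipeline()`, `reproduce()`).

## Worked example

Analytic accuracy of the double-well model against simulation, and the
working-memory noise bound:

```r
library(dwell)

pot <- potential_spec("double_well", mu = 0.15, alpha = 1)
kramers_accuracy(pot, sigma_total = 0.25, T_over_tau = 10)
#> <kramers_prediction> mu = 0.15, alpha = 1, sigma = 0.25, T = 10 tau
#>   P0 = 0.7257  p_C = 0.0301  p_E = 0.0000  P = 0.7340

run_psychometric(pot, mu_grid = 0.15, sigma_s_grid = c(0.25, 0.45),
                 T_grid = 2, n_trials = 4000,
                 config = integrator_config(sigma_i = 0), seed = 1)
#>     mu sigma_s T accuracy     se    n
#> 1 0.15    0.25 2  0.74125 0.0069 4000
#> 2 0.15    0.45 2  0.75775 0.0068 4000

delay_noise_bound(alpha = 0.70, tau_s = 3.3, delay_s = 1.08)
#> [1] 0.3247364
```

Reading the numbers: at `σ = 0.25` the theory predicts accuracy 0.734 —
mostly the first-visit probability (`P0 = 0.726`) plus a small correcting
boost (`p_C = 0.03`, `p_E ≈ 0`) — and the 4000-trial simulation agrees
(0.741 ± 0.007). Accuracy at the *larger* fluctuation magnitude 0.45 is
*higher* (0.758): the non-monotonic regime. The last line is the largest
internal noise for which attractor switches during the longest (1.08 s)
memory delay stay below 1% at the two-pulse task's fitted parameters
(`α = 0.70`, `τ = 3.3 s`): σ_I^max ≈ 0.32.

Fitting a two-pulse condition table (here simulated from known parameters):

```r
tab <- simulate_condition_table(c(k = 0.012, alpha = 0.70, sigma = 0.52, tau = 3.3),
                                design = two_pulse_design(n_per_condition = 10000),
                                seed = 42)
fit <- dwm_fit(tab, seed = 43)
summary(fit)
```

Note the scaling degeneracy documented in the methods vignette
(`vignettes/double-well-dynamics.Rmd`): only `α²/σ²`, `k/α^{3/2}` and `α/τ`
are identifiable from accuracy data, so per-parameter intervals are wide
along the ridge while those combinations are pinned tightly.

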