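---
title: "Attractor dynamics of perceptual evidence integration: models, theory, and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor dynamics of perceptual evidence integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In a fixed-duration binary discrimination task, an observer watches a noisy
stimulus for `T` seconds and reports a category. The classical description is
a decision variable `x(t)` that accumulates the momentary evidence
`S(t) = mu + sigma_S * xi_S(t)` plus internal noise `sigma_I * xi_I(t)`:

    tau dx/dt = -phi'(x) + sigma_S xi_S(t) + sigma_I xi_I(t)

and the choice is `sign(x(T))`. The potential `phi` encodes the integration
rule:

* `phi = 0` — perfect integrator (PI): uniform weighting of the whole
  stimulus;
* `phi = -mu x` with absorbing bounds (DDMA): early evidence dominates
  (primacy), because the variable freezes at the first bound crossing;
* the same with reflecting bounds (DDMR): late evidence dominates (recency),
  because early evidence saturates at the bound and is forgotten;
* `phi = -mu x - alpha x^2 + x^4` — the double-well attractor model (DWM):
  two attractors at roughly `x = +/- sqrt(alpha/2)` separated by a barrier of
  height `alpha^2/4` (at `mu = 0`), the reduced description of a
  winner-take-all cortical network. (Some treatments write the quadratic
  coefficient as `c2 = -alpha`; a published `c2 = -0.8` is `alpha = 0.8`
  here.)

The package's point is the behaviour of the double-well model *between* the
classical regimes: as the stimulus fluctuation magnitude `sigma_S` (or the
duration) grows, the model crosses over from primacy (the first attractor
visit sticks) through a *flexible categorization* regime (fluctuations are
strong enough to correct an initially wrong categorization but rarely strong
enough to corrupt a correct one) to recency (frequent transitions, only the
late stimulus matters). Because the correcting and error-generating
transition rates differ exponentially in the barrier-height difference, there
is a window where extra stimulus noise *increases* accuracy: the psychometric
curve `P(sigma_S)` is non-monotonic. The same mechanism produces a
non-monotonic double-pass choice consistency, and lets the model hold a
categorical decision across a working-memory delay.

## Simulation engine

`simulate_trials()` integrates all trials of an ensemble in lock-step with
the Euler-Maruyama scheme

    x <- x + dt/tau * (-phi'(x)) + sqrt(dt/tau) * (sigma_I xi_I + sigma_S xi_S)

with `dt = tau/40` and `tau = 200 ms` by default. Frame-based stimuli couple
in two ways, recorded in the `dwell_stimuli` object:

* *white* (Gaussian and zero-integral ensembles): frames live on the
  integrator grid; the per-trial mean enters like a drift (`dt/tau * mu_i`)
  and the deviations like white noise (`sqrt(dt/tau) * (S - mu_i)`), so the
  integrated fluctuation variance is step-size independent;
* *drift* (two-disc brightness ensembles, 100 ms frames): the frame value
  replaces the drift itself (`dt/tau * S(t)`) and the engine's own stimulus
  noise is zero — the frame sequence *is* the evidence.

Transition bookkeeping uses a full-hysteresis detector: a trial enters an
attractor when `x` crosses the attractor position, and a switch is counted
only when the opposite attractor position is subsequently crossed. This
matches the two-state abstraction of the theory and is immune to chatter
around the unstable point. Choice ties at exactly `x(T) = 0` are broken by a
seeded fair coin. Every noise role (stimulus generation, internal noise,
tie-breaks, connectivity, bootstrap) draws from its own named substream of
the experiment seed, so regenerating one ingredient never perturbs another.

Degenerate inputs: a non-finite `x` (step too large) aborts with the trial
index; `dt > tau/10` is rejected at configuration time; zero-variance rows in
the zero-integral generator are redrawn from the next substream counter with
a message.

## Psychophysical kernels

`compute_pk()` removes each trial's generative mean and computes, per frame
bin, the rank-based AUROC between the fluctuation distributions conditioned
on the two choices. Summary indices:

* `npka()` — the trapezoidal area of `PK - 0.5`, normalized by the same area
  for an ideal observer (perfect integration of the same stimulus ensemble
  with zero internal noise): 1 = ideal use of the fluctuations, 0 = none.
* `pk_slope()` — the kernel is normalized to unit area and fit with a line
  whose slope is scaled by `1/(2 var(t))` (population variance of the bin
  centers), mapping pure primacy to -1 and pure recency to +1. Kernels with
  an opposite-sign lobe can push the raw index slightly outside that range;
  the returned value is saturated at +/-1 with the raw value kept as an
  attribute.

For stimuli on the fine integrator grid the kernel is binned (`bin_s`
argument); `tau/10` to `tau/2` are sensible widths, trading temporal
resolution against per-bin counts. The stated bin width in any analysis here
is a package choice — the published kernels do not state one for
non-frame-based stimuli. Bootstrap errors (`bootstrap_pk()`) resample trials
jointly (stimulus and choice together), preserving their dependence.

## Kramers-rate accuracy theory

For the double-well model the package computes analytically:

* the first-visit probability `P0` (`first_visit_probability()`): by default
  the closed form obtained by dropping the quartic term — a ratio of error
  functions with scale `sqrt(2 alpha)/sigma` and shift `mu/(2 alpha)`; the
  exact splitting probability (quadrature of `exp(2 phi/sigma^2)`, integrand
  rescaled by its maximum) is available as `method = "quadrature"` and is
  what the simulation-comparison tests use. As printed in the source
  analysis, the closed form's denominator orientation yields negative values;
  the orientation consistent with the defining integral is implemented. The
  closed form deviates from the exact integral by a few percent at moderate
  noise (tests document ~2-3% at `mu = 0.15`, `sigma = 0.3-0.4`).
* the transition rates (`transition_rates()`): Kramers' formula with
  curvature prefactor `sqrt(|phi''(x_att) phi''(x_U)|)/(2 pi)` and exponent
  `-2 (phi(x_U) - phi(x_att))/sigma^2`, per unit dimensionless time `t/tau`;
  divide by `tau` for rates per second. The widely quoted small-tilt ratio
  `k_C/k_E = exp(4 mu sqrt(alpha/2)/sigma^2)` omits the O(mu) prefactor
  ratio and is already ~5% off at `mu = 0.05`, `alpha = 1`; the tests verify
  it where the expansion parameter `mu/alpha^{3/2}` is genuinely small.
* the per-trial transition probabilities and accuracy
  (`trial_transition_probs()`, `kramers_accuracy()`):
  `P = P0 (1 - p_E) + (1 - P0) p_C`, algebraically equal to
  `P0 e^{-kT} + P_inf (1 - e^{-kT})`; both forms are computed and must agree
  to 1e-12.

Fixed points are the numerical roots of the cubic `phi'(x) = 0`; note that
expanding around the origin gives the unstable point at `-mu/(2 alpha)` to
first order (a printed variant with `4 alpha` in the denominator does not
satisfy the cubic). The barrier disappears at the saddle-node tilt
`mu_sn = (4 alpha/3) sqrt(alpha/6)`; the closed-form threshold
`mu_C = (alpha/2) sqrt(alpha/2)` below which `P(sigma_S)` has an interior
maximum is itself a small-`mu` approximation — the numerical scan
(`accuracy_peak()`) locates the actual disappearance slightly above it. The
Kramers approximation is trusted when the smaller barrier exceeds
`2 sigma^2`; `kramers_accuracy()` flags (rather than hides) points outside
that region.

The delay analysis uses the symmetric chain at `mu = 0`:
`p_switch(d) = (1 - exp(-2 k_sym d/tau))/2`, and `delay_noise_bound()`
root-finds the internal noise at which this reaches a criterion (1% at the
1.08 s maximal delay reproduces the published bound of 0.32 at the fitted
parameters, with the implied internal-to-stimulus noise ratio 0.78).

## Double-pass consistency

`double_pass()` presents each frozen zero-integral stimulus `n_passes` times
with independent internal noise. Per stimulus the probability that two
passes agree is estimated by the unordered concordant-pair fraction
`(choose(m,2) + choose(n-m,2))/choose(n,2)` — the unbiased U-statistic; the
plug-in `p^2 + (1-p)^2` is biased upward by `2 p(1-p)/n`. The default
`n_passes = 20` exploits the fact that the package controls the generative
process (the strict experimental protocol is `n_passes = 2`); the published
protocol's pass count and stimulus count are not stated, so the defaults here
(150 stimuli, 20 passes) are package choices. The companion diagnostic
`transition_diag()` estimates the per-trial switch probability on identical
stimuli with and without internal noise; its difference peaks exactly where
consistency dips — the regime where transitions need internal and stimulus
fluctuations to cooperate.

## The two-pulse working-memory estimator

`dwm_fit()` is the package's central estimator. A condition table of
single-pulse (coherences 0–51.2%) and double-pulse (3.2/6.4/12.8% crossed,
congruent, 120 ms pulses) trial counts is pooled across delays (accuracy is
empirically delay-independent up to ~1 s) and fit by maximizing the binomial
log-likelihood `sum N_C log P + N_E log(1 - P)` with Nelder-Mead from
Latin-hypercube starts in a box, on a logistic reparameterization so the box
binds. A published variant of the objective written as a *linear* form
`sum N_C P + N_E (1-P)` is not a log-likelihood (its optima sit at P in
{0,1}); it is kept behind `form = "printed"` for comparison only.

Condition accuracies are closed-form: a pulse at coherence `coh` tilts the
potential by `mu = k coh`; the first pulse seeds the two-state chain with the
first-visit probability at `x0 = 0` and each pulse then applies the
correcting/error transition probabilities over `T = 0.12 s / tau`. Beyond the
saddle-node tilt (only the 51.2% single pulses at the published `k`) the
accuracy is the exact splitting probability between the zero-tilt attractor
positions, with transitions absent. `tau` is interpreted in seconds — the
interpretation under which the delay-switch bound reproduces the published
0.32 — and the same `t/tau` rate scaling is used for pulses and delays.

Two structural findings, established during development and worth knowing
before interpreting fits:

1. **A scaling ridge.** The map `(alpha, sigma, k, tau) -> (c alpha, c sigma,
   c^{3/2} k, c tau)` leaves every condition accuracy invariant (rescale
   `x` by `sqrt(c)` and time by `c`), so only `alpha^2/sigma^2`,
   `k/alpha^{3/2}` and `alpha/tau` are identifiable from accuracy data — and
   the third only through the tiny within-pulse transition probabilities.
   Consequently the Hessian is singular along the ridge; `dwm_fit()` inverts
   it by eigenvalue flooring, so the per-parameter 95% intervals honestly
   become very wide along the ridge while the identifiable combinations are
   pinned tightly (parameter-recovery tests check both). Published
   per-parameter intervals of a few percent for this model should be read
   with this degeneracy in mind.
2. **Pulse-order asymmetry.** Under the printed two-state chain with
   `tau ~ 3.3 s`, a 120 ms pulse carries transition probabilities of at most
   a few percent, so the first pulse — which sets the initial attractor —
   dominates: reversed pairs with the stronger pulse first score *higher*,
   and per-trial simulations from the fitted model give a *negative*
   primacy-recency index. A recency-leaning fitted model is not reproducible
   from these equations with the same time scaling that yields the delay
   bound; the package implements the equations as printed and documents the
   tension rather than adjusting either analysis.

`delay_robustness()` contrasts the fitted attractor model with a perfect
integrator carrying an analog memory: the attractor accuracy is flat in the
delay whenever the internal noise is below `sigma_I^max`, while the
integrator accuracy
`Phi(mu_tot T_p / sqrt(tau (2 T_p sigma^2 + d sigma_I^2)))` (with
`mu_PI = 0.44 k coh`, the scaling that matches the attractor model at zero
delay) decays for every delay — the diffusion-variance bookkeeping in that
expression is this package's construction, chosen to make the comparison at
matched noise explicit.

## Synthetic stimulus generators

All analyses run on synthetic data; the generators define the study
conditions:

* `gaussian_frames()` — i.i.d. Gaussian evidence per integrator step.
* `zero_integral_frames()` — rows z-scored with the population standard
  deviation, so every trial has exactly zero integrated evidence and
  fluctuation magnitude exactly `sigma_S` (two frames give exactly
  `+/- sigma_S`).
* `brightness_disc_frames()` — the two-disc brightness design: 100 ms
  frames, five equal segments, an evidence pulse in 80% of trials
  compensated exactly across the remaining segments (hence anticorrelated
  segments). The luminance-to-evidence scaling of the original experiment is
  not published, so the generator is structural, not calibrated; its
  defaults (`gen_mean_gap = 0.05`, `frame_sd = 0.3`, `pulse_size = 0.2`)
  were chosen once, a priori, by the Kramers calculation: with the published
  model parameters (`alpha = 0.8`, `sigma_I = 0.3`, `tau = 200 ms`) the
  effective white-noise magnitude `frame_sd * sqrt(0.1/tau)` puts the total
  transition rate near `1/T` between `T = 2` and `3 s`, so the kernel-slope
  crossover lands inside the tested 1–5 s range at intermediate accuracy.
* `two_pulse_design()` — the published condition grid (6 single-pulse
  levels; 9 coherence sequences crossed with 4 delays).
* `ou_currents()` — Ornstein-Uhlenbeck stimulus currents (exact transition
  density, not Euler) for the spiking network.

What the generators deliberately do not emulate: actual visual stimuli,
subject lapses, response bias, or any luminance calibration. Tests passing on
these ensembles show that the *analysis machinery and model behaviour* are
correct under the stated generative assumptions, not that real observers
behave this way.

## Spiking winner-take-all network

`build_network()`/`run_trial()` implement a current-based
leaky-integrate-and-fire network: two selective excitatory populations and a
shared inhibitory population, sparse random connectivity (`eps = 0.1`),
exponential synapses with a 0.5 ms delay, instantaneous external Poisson
synapses, Euler step 0.1 ms, and a common stimulus current per excitatory
population (`I0 (1 +/- mu)` plus OU fluctuations, 20 ms correlation time).
The published network's weight table is not available, so the constants here
were set by a documented tuning procedure with two criteria: (a) with no
stimulus drive the network is quiescent and symmetric; (b) with the baseline
current on, a transient kick to one population leaves it firing at a high
rate (> 20 Hz) at least 1 s after kick offset while the other is suppressed
— winner-take-all bistability near the instability of the symmetric state.
During tuning, the external drive's shot noise had to be reduced (smaller
jumps at higher rate) before a robust bistable window in `J_EE` appeared;
the shipped defaults sit in the middle of that window. Slow (20 ms)
recurrent excitation stabilizes the attractors at the reduced size.

The default scale divides the reference populations (1000/500) by 5 and
multiplies the recurrent weights by 5, preserving the mean recurrent drive.
At this scale finite-size fluctuations are ~sqrt(5) stronger than at the
reference size, which compresses (but does not destroy) the
beneficial-fluctuation window: at `mu = 0.1`, `T = 3 s` the accuracy versus
`sigma_S` curve dips near 9 pA and peaks near 12 pA before decaying, and the
kernel slope increases both with `sigma_S` and with duration. Only these
orderings are asserted — exact values depend on the unpublished constants.
The tests use a few hundred trials per cell; the published figures used
thousands at full scale.

## n-choice rate network

`simulate_ratenet()` integrates the standard coupled rate equations for 3 or
4 excitatory populations competing through one inhibitory unit, with the
piecewise transfer function (0; x^2 on [0,1]; `2 sqrt(x - 3/4)` above) and
the published couplings (`s = 0.694`, `c = g = sqrt(5)`, `I = 2.25`,
`dI = 0.03 s`). Noise enters Euler steps as `sigma sqrt(dt/tau) xi` — the
same convention as the diffusion engine; the source of the published noise
amplitudes does not state its convention or trial duration. A known
limitation: under these printed parameters and this convention the accuracy
versus noise sweep is monotone decreasing from ceiling for durations between
0.5 and 6 s — the beneficial-fluctuation window reported for the multi-choice
extension did not reproduce here, and no parameter was adjusted to force it.
The unit tests therefore assert the symmetric-input, zero-noise, label- and
continuity properties only.

## Problem sizes and numerical choices in the shipped tests

The test suite runs the full analysis stack at desk scale: 4,000–10,000
diffusion trials per psychometric cell, 3,000 trials per kernel with 200
bootstrap resamples, 150 stimuli x 20 passes per consistency point, 100
two-pulse refits for interval coverage at 800 trials per condition, and a
few hundred spiking trials per cell at the reduced network size. These are
package choices balancing statistical resolution of the asserted effects
against a desk-scale runtime; all assertions are made at tolerances derived
from the binomial or bootstrap error of the quantity under test.

## Known limitations

* The Kramers chain is quantitative only where the smaller barrier exceeds
  about `2 sigma^2`; outside, predictions are flagged, not asserted.
* The erf first-visit form inherits a few-percent bias at moderate noise;
  use `method = "quadrature"` where that matters.
* The two-pulse model is structurally non-identifiable along the scaling
  ridge described above; report the identifiable combinations when comparing
  fits.
* The spiking and rate networks use package-chosen constants where the
  published tables are unavailable; only qualitative regime structure is
  claimed, and the multi-choice beneficial-fluctuation effect is an open
  discrepancy under the printed parameters.
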