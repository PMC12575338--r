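---
title: "Disambiguating system and observer effects with state noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disambiguating system and observer effects with state noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sysobs)
```

## The problem

When one neural process is recorded simultaneously by two devices — say
microwire local field potentials and macroelectrode iEEG on the same hybrid
depth electrode, summarized as high-frequency broadband (HFB) power — the
two time series never agree exactly. The disagreement can have two very
different sources:

* **system effects**: the latent dynamics genuinely differ between the
  spatial scales each device samples;
* **observer effects**: the latent dynamics are the same, but each device
  imposes its own (generally nonlinear) transformation on the signal.

sysobs implements a generative framework in which these two explanations
are explicit, competing models, and in which *state noise* — random input
shared by both scales — is the probe that separates them.

## Generative model

Each scale has a scalar latent state driven by a common exogenous input
$\upsilon(t)$ through linear time-invariant dynamics:

$$\dot x_\mu = a\,x_\mu + b\,\upsilon, \qquad
  \dot x_M = (a + \delta a)\,x_M + b\,\upsilon ,$$

and each device converts its latent state into a recorded signal through a
sigmoidal observer with additive measurement noise:

$$h_\mu = c\,\tanh(k\,x_\mu) + \varepsilon, \qquad
  h_M = c\,\tanh\big((k + \delta k)\,x_M\big) + \varepsilon' .$$

All cross-scale structure lives in two deviation parameters: $\delta a$
(a *system* difference) and $\delta k$ (an *observer* difference). The two
reduced models pin one of them to zero:

* **identical observers** ($\delta k = 0$): all variation is dynamical;
* **identical systems** ($\delta a = 0$): all variation is observational.

For a deterministic model, the derivative of the observed difference is
$\dot h_\mu - \dot h_M = g_\mu' f_\mu - g_M' f_M$, a product of observer
sensitivity and system flow — the two factors are confounded. Adding
Stratonovich state noise $s(x)\,\xi$ to each state equation splits the
derivative into that same degenerate part plus a term
$\sigma_\mu \xi_\mu g_\mu' - \sigma_M \xi_M g_M'$ that depends on the
observer sensitivities *only*. `stratonovich_terms()` computes both pieces
along a simulated path; the package's stochastic simulations use the Heun
predictor–corrector, which converges to the Stratonovich solution without a
drift correction, and store their Wiener increments so the decomposition is
exact up to integrator truncation.

```{r decomposition}
drv <- scene_driver(random_scene_boundaries(8, 4, seed = 1), seed = 1) |>
  add_fluctuations(noise_sd = 0.1, smooth_width = 0.05, seed = 1)
p <- gen_params(delta_a = 0.5, obs_noise_sd = 0)
lat <- simulate_latent(drv, p, noise_spec("additive", seed = 1))
head(stratonovich_terms(lat, p))
```

## The exogenous driver

The driver emulates a movie stimulus: scenes of random length are each
assigned an independent Uniform(0, 1) value, giving a piecewise-constant
signal; Gaussian noise plus light Gaussian-kernel smoothing (SD 50 ms by
default, reflective boundaries) adds the fast fluctuations of real sensory
input. The kernel width and the noise SD (default 0.1 in driver units) are
package choices — only "light temporal smoothing" has an external anchor —
and the smoothing is exact on constant signals, so scene plateaus keep
their means.

## Model inversion

The posterior over $(\delta a, \delta k)$ is obtained by variational
Laplace: Gauss–Newton ascent with Levenberg–Marquardt damping on the joint
log density, with gradients and curvature by central finite differences
(step $10^{-4}$; the model has two or three free parameters, so robustness
is worth more than speed). The free energy is the Laplace approximation to
the log evidence,

$$F = \log p(y \mid \hat m) + \log p(\hat m)
      + \tfrac12 \log\det(2\pi\Sigma),$$

equivalently accuracy minus complexity with complexity
$\mathrm{KL}[q \,\|\, p] \ge 0$. A proposed step is accepted only if it
does not decrease $F$, so $F$ is monotone over accepted iterations;
convergence is declared after three consecutive accepted steps with
$|\Delta F| < 10^{-3}$ nats (at most 64 iterations), or when eight
consecutive proposals fail to improve an already-converged-scale $F$.
This construction is exact for conjugate linear-Gaussian models, which is
how the optimizer is validated in the test suite.

The likelihood is a prediction-error decomposition:

* **deterministic mode**: independent Gaussian residuals between the data
  and the noise-free forward simulation;
* **additive / multiplicative modes**: a continuous–discrete extended
  Kalman filter with Heun mean propagation, a linearized covariance
  propagator matched to the Heun mean map, process-noise intensity
  $\sigma^2$ (or $\sigma^2 x^2$), and observation Jacobian
  $c\,k\,\mathrm{sech}^2(kx)$. When the two scales share one Wiener path
  (the default reading of the stochastic model), the process-noise
  covariance is rank one across channels, which is exactly what lets the
  filter attribute common fluctuations to differential observer
  sensitivity. For multiplicative noise the filter drift carries the
  Stratonovich-to-Itô correction $a + \sigma^2/2$ so the mean propagation
  matches the generator's convention.

Priors are standard normal on $\delta a$ and $\delta k$. Observation
precision is estimated by default as one shared log-precision
hyperparameter with hyperprior $\mathcal N(2, 4)$ nats — wide enough to be
uninformative over the plausible range while keeping the problem
well-posed. Volatilities $\sigma_\mu, \sigma_M$ are fixed, not estimated.

## Model comparison

Reduced models are scored by Bayesian model reduction: the fitted posterior
is re-scored under a modified prior without refitting. Pinning a parameter
(prior mean and variance zero) is implemented as the Savage–Dickey ratio —
the log ratio of posterior to prior marginal density at zero — which is the
exact zero-variance limit of Gaussian reduction and numerically stable;
non-degenerate reduced priors use the closed-form canonical-parameter
expression. Free energies become model probabilities by softmax under a
uniform model prior; the losing model's probability is the reported
"significance".

```{r softmax}
model_probabilities(c(identical_observers = log(19), identical_systems = 0))
```

## Default study conditions

The synthetic generator emulates two z-scorable channels of 1000 samples at
250 Hz (a 4 s window) driven by an 8-scene stimulus. Parameter values the
external description leaves unstated are fixed package choices, chosen once
to give visibly different channels with stable, well-conditioned dynamics:

| parameter | default | units | role |
|---|---|---|---|
| $a$ | $-1$ | 1/s | intrinsic rate (1 s time constant) |
| $b$ | 1 | – | input gain |
| $c$ | 1 | signal | observer saturation level |
| $k$ | 1 | 1/state | observer input gain |
| $\delta a$ or $\delta k$ | 0.5 | as above | scenario effect size |
| $\sigma_\mu, \sigma_M$ | 0.2 | state/$\sqrt{\mathrm s}$ | volatility (stochastic modes) |
| obs. noise SD | 0.05 | signal | measurement noise |

## Decisions where the design was open

* **Shared vs independent Wiener paths.** The stochastic model is written
  once with a single noise process and once with per-scale processes. The
  default is a shared path (`shared_increments = TRUE`), which makes the
  observer-only decomposition sharpest; independent paths are selectable.
* **Scene values.** Scenes receive seeded Uniform(0, 1) draws both for
  synthesis and for the empirical design matrix, with an ordinal-index
  option (`values = "ordinal"`), since only "a unique value per scene" is
  specified externally.
* **Calibration target.** `grid_search_calibrate()` defaults to averaging
  both channels' MSEs, but the subject workflow calibrates $(a, c, k)$
  against the micro channel: those parameters *are* the micro-scale
  baseline, and joint calibration lets the baseline absorb the cross-scale
  deviation the inversion is supposed to estimate.
* **Standardized empirical likelihood.** Preprocessing z-scores each
  channel, which deletes amplitude and offset information. The subject
  workflow therefore compares standardized waveforms in its deterministic
  likelihood; stochastic subject inversions instead map the channels
  affinely onto the calibrated model's output scale.
* **Multiple subjects.** Across included subjects the losing-model
  probability is Bonferroni-corrected (the external correction is
  unspecified).

## Numerical choices

Fixed step $dt = 0.004$ s (the data rate). Initial states are zero, with a
testing override. A state exceeding $10^6$ aborts the simulation with the
step index; divergent grid points in calibration score $+\infty$ and ties
break to the first point in lexicographic order. Filter covariances that
lose positive definiteness are repaired by flooring eigenvalues at
$10^{-12}$; genuinely zero covariance (deterministic filtering) is left
untouched, so the additive filter with $\sigma = 0$ reproduces the
deterministic likelihood exactly. Zero-variance residuals in the
diagnostics have skewness 0 and AC1 0 by definition; skewness is the
bias-corrected (adjusted Fisher–Pearson) estimator.

## What the synthetic experiments do and do not show

`run_synthetic_validation()` generates data from each reduced model, inverts
the full model, and reduces to both candidates across seeds and noise
modes; with the defaults above, selection is correct in every scenario and
noise mode, with losing-model probabilities far below conventional
thresholds. The test suite runs this at 5–20 seeds per cell; the
acceptance script uses 20 seeds per scenario.

Two caveats matter when carrying these results to real recordings. First,
the generator shares the analysis model's functional form, so passing tests
demonstrate *identifiability under the model*, not robustness to
misspecified observers — an incorrectly assumed nonlinearity can masquerade
as a system effect. Second, the size of the evidence gap between reduced
models depends strongly on the identification regime. Under these default
conditions the deterministic model is itself almost perfectly identified
(observation noise 0.05 over 1000 samples), and the validation summary
shows a *larger* mean evidence gap for deterministic than for
additive-noise inversions: modeled state noise widens the posterior and
caps the gap at the noise-limited information, while the deterministic gap
grows without bound as observation noise shrinks. The benefit of state
noise reported for empirically calibrated regimes — where deterministic
identification is marginal — should therefore be read as regime-dependent;
`run_synthetic_validation()` reports the per-mode gaps (`noise_gain`) so
the regime can be checked rather than assumed.

The empirical-mode pipeline (`run_subject_analysis()`) covers only the
final preprocessing steps (decimation, z-scoring, truncation); spectral
power extraction, re-referencing and artifact handling are upstream of this
package, and the observers are mathematical stand-ins, not electrode
physics.
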