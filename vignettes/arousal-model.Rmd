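---
title: "A mixed-observation state-space model for sympathetic arousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mixed-observation state-space model for sympathetic arousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Sympathetic arousal is not directly observable, but it leaves traces in
several peripheral signals at once. This package treats arousal as a scalar
latent state $x_k$ sampled at 4 Hz ($t_s = 0.25$ s) that evolves as a
first-order autoregression driven by external stimulus impulses:

$$x_k = \rho\, x_{k-1} + \alpha\, I_k + \varepsilon_k,
  \qquad \varepsilon_k \sim N(0, \sigma_\varepsilon^2),$$

where $I_k \in \{0,1\}$ marks stimulus onsets (conditioned cues, shocks).
Four observation streams are tied to this one state:

1. **SCR events** $m_k \in \{0,1\}$: a skin-conductance response peak is
   present or absent at sample $k$. The event probability follows a logit
   link, $\mathrm{logit}(p_k) = \beta_0 + \beta_1 x_k$.
2. **Phasic-derived amplitude** $r_k$ (log-µS): a cubic interpolation of the
   log phasic peak amplitudes, modelled as
   $r_k = \gamma_0 + \gamma_1 x_k + v_k$, $v_k \sim N(0,\sigma_v^2)$.
3. **Tonic level** $s_k$ (µS): $s_k = \delta_0 + \delta_1 x_k + w_k$,
   $w_k \sim N(0,\sigma_w^2)$.
4. **Heartbeats**: R peaks binned at $\Delta = 5$ ms ($J = 50$ bins per state
   sample) form a binary point process. The RR-interval density is a
   history-dependent inverse Gaussian (HDIG): given the last beat at $u_l$
   and the previous $q$ intervals $h_l, \dots, h_{l-q+1}$, the waiting time
   is inverse Gaussian with mean
   $\mu = \theta_0 + \sum_{i=1}^{q} \theta_i h_{l-i+1} + \eta\, x_k$ and
   shape $\theta_{q+1}$. The conditional intensity is
   $\lambda = g / (1 - G)$ with $g$, $G$ the inverse-Gaussian density and
   distribution function. A negative $\eta$ encodes that arousal shortens RR
   intervals (accelerates the heart).

## State estimation

The forward filter propagates a Gaussian approximation to
$p(x_k \mid \text{data up to } k)$. The predict step is the usual AR(1)
moment propagation. The update step mixes all four channels: the two
Gaussian channels enter linearly, while the Bernoulli and point-process
terms make the filtered mean a fixed point of a one-dimensional nonlinear
equation, solved by damped Newton iteration (start at the predicted mean,
step tolerance $10^{-8}$, at most 50 iterations, halving on divergence,
bisection fallback on a $\pm 50$ bracket). The filtered variance is the
inverse local curvature: prior precision plus the Fisher information of the
Bernoulli term plus the Gaussian-channel precisions minus the point-process
curvature term. Fixed-interval smoothing is the standard backward recursion
with gain $A_k = \rho\, \sigma^2_{k|k} / \sigma^2_{k+1|k}$.

Initialization is $x_{1|1} = 0$, $\sigma^2_{1|1} = \sigma_\varepsilon^2$,
consistent with the assumption that arousal starts near zero (the same
assumption that justifies the empirical $\beta_0$). When the binary and
point-process channels are uninformative ($\beta_1 = 0$, $\eta = 0$) the
filter and smoother coincide with the textbook Kalman filter and RTS
smoother to $10^{-10}$; the test suite pins this equivalence against an
independent implementation.

## Parameter estimation

An EM loop alternates state estimation (E-step) with parameter updates:

* $\rho, \alpha$ solve a 2-by-2 normal-equation system built from the
  smoothed second moments $U_k = x_{k|K}^2 + \sigma^2_{k|K}$ and
  $U_{k,k+1} = x_{k|K} x_{k+1|K} + A_k \sigma^2_{k+1|K}$;
  $\sigma_\varepsilon^2$ follows in closed form. An optional constraint
  clamps $\alpha \ge 0$ (a stimulus should not lower arousal).
* Each Gaussian channel's intercept/slope/variance has a closed-form update.
* $\beta_0, \beta_1$ follow one of two strategies. The *empirical* strategy
  (default for simulation studies) fixes $\beta_1 = 1$ and
  $\beta_0 = \mathrm{logit}(\hat p_0)$ with $\hat p_0$ the observed event
  rate, held constant. The *Taylor* strategy re-solves two second-order
  approximate score equations each iteration with a damped Newton root
  finder; it is convergence-sensitive (the coefficients sit in exponents),
  so failures keep the previous iterate with a warning.
* The heartbeat parameters use a two-step strategy because joint M-step
  maximization over $\theta$ and $\eta$ is prohibitively slow: first
  $\theta_0,\dots,\theta_{q+1}$ are fitted offline by maximum likelihood
  with $\eta = 0$ (BFGS with analytic gradients on a log-shape
  parameterization, method-of-moments start, Newton polish to gradient norm
  $< 10^{-6}$); then $\eta$ is chosen from the grid
  $\{-10^{-6}, \dots, -10^{-1}\}$ by running the full EM at each value and
  maximizing the approximate expected point-process log likelihood
  $\bar Q_2$ (plug-in log likelihood at the smoothed mean plus a
  second-order variance correction), subject to the post-fit time-rescaling
  KS distance staying within the 95% band (a configurable 10% slack covers
  "reasonably close"; ties within $10^{-6}$ go to the smallest $|\eta|$).

Convergence is declared when the mean absolute parameter change drops below
the tolerance (default $10^{-5}$). For experimental recordings the
continuous channels are divided by their standard deviations and an
overfitting gate monitors $|\sigma_v^2 - \sigma_w^2|$: when the next update
would push it below 0.1 — the signature of the state collapsing onto one
continuous channel — iteration stops early and the last pre-gate iterate is
returned. Simulation-study runs skip standardization and the gate.

Per-iteration logs include $\bar Q_1$ (Bernoulli), $\bar Q_2$ (point
process) and the expected state/Gaussian-channel log likelihood. The
Gaussian posterior approximation voids a strict ascent guarantee, so the
suite asserts a non-decreasing trend of the *total* surrogate in at least
90% of iterations rather than monotonicity of any partial sum.

## Time-rescaling goodness of fit

Integrating the conditional intensity across each RR interval yields
unit-rate exponential variables when the intensity is correct;
$1 - e^{-z}$ maps them to uniforms whose sorted values are compared with
mid-point uniform quantiles. The KS distance (maximum deviation from the
45° diagonal) is compared with $1.36/\sqrt{L}$. Because the HDIG history is
fixed within an interval and the arousal state is piecewise constant on the
4 Hz grid, the integral is computed piecewise exactly as differences of the
log survival function — no quadrature error. Survival probabilities are
evaluated through a cancellation-free form of the inverse-Gaussian
distribution function (upper normal tail plus log-scale exponential term),
which keeps the intensity and its derivatives accurate deep into the tail.

Model order selection fits $q = 1..8$ by maximum likelihood and picks the
smallest KS distance, with ties to the smaller order, alongside the partial
autocorrelation of the RR intervals for reporting. A caveat established by
the simulation tests: because the shape parameter is refit at every order,
the KS distance measures marginal calibration and discriminates the *order*
only weakly — on generator-drawn data the distances across orders differ by
about as much as their sampling noise. This mirrors the heterogeneous
orders such selection yields across real subjects, and is why the package
also reports the partial autocorrelation and the per-order table rather
than trusting the argmin alone.

## The simulator

`make_dataset()` draws from the exact generative structure: AR(1) state with
impulses, Bernoulli events, Gaussian channels, and HDIG heartbeats drawn
sequentially (inverse-Gaussian variates via the Michael–Shucany–Haas
transform). Default conditions are the package's simulation-study regime:
$K = 2000$ samples (500 s), 25 stimulus impulses placed uniformly with a
minimum 10 s spacing, baseline event probability $p_0 = 0.01$
($\beta_0 = -4.5951$), $\rho = 0.995$, $\alpha = 0.04$,
$\gamma = (0.35, 0.4)$, $\sigma_v^2 = 0.002$, $\delta = (-0.7, 0.2)$,
$\sigma_w^2 = 0.003$, $\sigma_\varepsilon^2 = 0.03$, order-2 HDIG with
$\theta = (0.27432, 0.83697, -0.10511)$, shape $234.22144$, and
$\eta = -0.005$. The 500 s length and the stimulus spacing are the
package's own choices (they produce recovery errors on the scale a study of
this design reports); the remaining values are the study conditions.

Two generative conventions are worth noting. The arousal value entering an
interval's mean is frozen at the sample containing the previous beat — the
model defines a shifted-mean density per interval, not intra-interval state
variation. And a drawn mean that is nonpositive (possible in principle with
extreme couplings) is rejected and redrawn without the arousal term, with a
counter kept; at the default parameters this never triggers.

What the simulator does *not* emulate: raw ECG waveforms and raw
un-decomposed skin conductance (features are generated at the model's
observation level), motion artifacts, non-stationary baselines, or
stimulus-type-specific response amplitudes. Passing recovery tests on this
generator therefore validates the estimation machinery under the model's
own assumptions, not robustness to real-world preprocessing error.

## Preprocessing choices

Raw skin conductance is lowpass filtered at 0.5 Hz with a 4th-order
zero-phase Butterworth (forward-backward; phase distortion would shift SCR
peak times) and interpolated onto the 4 Hz grid. The tonic/phasic split is
a sparse-deconvolution fit: a non-negative sudomotor driver convolved with
a Bateman kernel (rise 0.7 s, decay 2.0 s) plus an unpenalized smooth
tonic basis, solved by L1-penalized least squares (glmnet). It reproduces
the model class of convex EDA decompositions without claiming numerical
equivalence to any specific implementation; externally computed components
are accepted unchanged, and the L1 shrinkage leaves a bounded
reconstruction residual (asserted below 0.15 µS on synthetic signals).
SCR events are phasic local maxima above 0.015 µS — strictly greater than
both neighbours, plateaus resolved to their first sample — and the
phasic-derived signal interpolates the log amplitudes through the peak
knots plus the first and last samples, flooring the phasic at $10^{-6}$ µS
before the log since decomposition residuals can dip to zero. R-peak times
are best supplied precomputed; the bundled detector (band-passed ECG,
robust threshold, 0.3 s refractory) covers clean recordings only.

## Numerical safeguards

* Event probabilities are clipped to $[10^{-10}, 1-10^{-10}]$ inside the
  Fisher-information term; $\lambda\Delta$ is clipped below $1 - 10^{-12}$
  in log terms (the Bernoulli-bin approximation requires
  $\lambda\Delta < 1$).
* Survival values below $10^{-12}$ in the intensity are clipped with a
  warning — far tails otherwise destabilize the Newton update.
* Bins preceding the first $q$ completed RR intervals have no defined
  history and are excluded from all likelihood sums.
* Two beats in one 5 ms bin (RR < 5 ms) raise an error: physiologically
  impossible, so it signals corrupted input.
* Variance updates are floored at tiny positive values; a nonpositive
  filtered precision raises an error naming the sample.

## Problem sizes

The test suite and the reproduction script run the recovery study at
$K = 2000$ (500 s, about 490 beats), with the $\eta$ grid evaluated on a
1000-sample segment and EM capped at 30–120 iterations depending on the
role of the run; calibration checks use 200 replicates. These sizes were
chosen so the whole study re-runs in minutes on one core while keeping the
recovery errors in the regime the design targets.

## Known limitations

* $\beta_1 = 1$ fixes the state scale only weakly; the Gaussian channels
  can trade slope against state amplitude, so $\sigma_\varepsilon^2$ and
  the channel slopes are recovered less sharply than $\rho$ and the noise
  variances. This is a property of the model, visible in any recovery run.
* The Taylor $\beta$ mode can fail to converge on rare-event series; it is
  intended for experimental fits where overfitting, not convergence, is the
  concern.
* KS-based order selection is weakly discriminating (see above).
* Stimulus-type-specific gains (separate $\alpha$ per condition) and
  alternative link functions are out of scope.
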