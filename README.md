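# arousaltrack

Track a latent sympathetic-arousal state from simultaneous skin-conductance
and heart-rate observations, for researchers working with Pavlovian fear
conditioning, psychophysiology, or affective wearable sensing.

Physiological markers of arousal are usually analyzed one at a time. This
package fuses four of them inside a single state-space model: an unobserved
arousal state `x_k` (4 Hz) follows an AR(1) recursion driven by stimulus
impulses,

    x_k = rho * x_{k-1} + alpha * I_k + eps_k,    eps_k ~ N(0, sigma_eps^2)

and generates

* binary skin-conductance-response (SCR) events through a logit link,
  `logit(p_k) = beta0 + beta1 * x_k`;
* a phasic-derived amplitude signal `r_k = gamma0 + gamma1 * x_k + v_k`
  (log-µS, cubic interpolation over the log SCR peak amplitudes);
* the tonic skin-conductance level `s_k = delta0 + delta1 * x_k + w_k` (µS);
* heartbeats as a binary point process in 5 ms bins, whose conditional
  intensity comes from a history-dependent inverse Gaussian (HDIG)
  RR-interval density with mean
  `mu = theta0 + sum_i theta_i * h_{l-i+1} + eta * x_k` and shape
  `theta_{q+1}`.

Estimation is a Gaussian-approximate Bayesian forward filter (Newton-solved
update), fixed-interval smoother, and an EM loop with closed-form M-steps;
the heartbeat parameters follow a two-step strategy (offline maximum
likelihood for `theta`, grid search over `eta` under a time-rescaling KS
goodness-of-fit constraint). A model-faithful simulator supports
parameter-recovery studies, and trial-analysis utilities provide
event-locked averages with one-tailed condition contrasts.

## Worked example

Simulate the default recovery regime (500 s at 4 Hz, 25 stimulus impulses),
refit the heartbeat history coefficients, and run the EM:

```r
library(arousaltrack)

d <- make_dataset(K = 2000, seed = 10)
d
#> Synthetic arousal dataset (seed 10 )
#> observation_set: K = 2000 samples at 4 Hz (500.0 s), 90 SCR events
#> heartbeat_series: 494 beats over 500.0 s (mean RR 1.010 s), 2000 x 50 bins of 5 ms
#>   stimuli: 25 impulses

th <- fit_hdig_ml(d$heartbeats$rr, 2)       # theta by offline ML, eta = 0
hd <- hdig_params(c(th$theta, th$shape), eta = -0.005)
fit <- run_em(d$obs, d$heartbeats, d$stimuli, hd, em_config(max_iter = 60))
fit$params$rho
#> [1] 0.9940964
fit$params$var_w
#> [1] 0.002889727
cor(fit$trajectory$x_smooth, d$x)
#> [1] 0.9985704
```

`rho` and the tonic noise variance come back close to the generating values
(0.995 and 0.003); the smoothed state tracks the simulated truth with
correlation above 0.99. The state scale itself is only weakly identified
(`beta1 = 1` pins it through the rare-event channel), so channel slopes and
`sigma_eps^2` absorb a scale trade-off — expected behavior for this model
class, discussed in the vignette.

Goodness of fit for the heartbeat model uses the time-rescaling theorem:

```r
z <- arousaltrack:::hdig_rescaled(d$heartbeats$beat_times, th)
kg <- ks_goodness(z = z)
c(kg$ks_distance, kg$bounds_95)
#> [1] 0.02244255 0.06137594   # inside the 95% band
```

Command-line use (writes CSV/JSON artifacts plus a run manifest):

```sh
Rscript inst/cli/arousaltrack simulate --seed 7 --out sim/
Rscript inst/cli/arousaltrack fit --obs sim/observations.csv \
    --beats sim/beats.csv --events sim/events.csv --eta -0.001 --out fit/
Rscript inst/cli/arousaltrack analyze --traj fit/trajectory.csv \
    --events sim/events.csv --out report/
```

Real recordings enter as plain tabular files: skin conductance
(`time_s,value` in µS) through `sc_pipeline()` (0.5 Hz lowpass, 4 Hz
resample, tonic/phasic split, SCR detection at 0.015 µS), and beat times
(one column, seconds) through `heartbeat_series()`.

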