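# Independent oracles used across the suite. These are deliberately naive,
# textbook implementations kept separate from the package internals.

# Scalar Kalman filter + RTS smoother for the linear-Gaussian submodel:
#   x_k = rho x_{k-1} + alpha I_k + eps,   eps ~ N(0, q)
#   r_k = g0 + g1 x_k + v,  v ~ N(0, vv);  s_k = d0 + d1 x_k + w, w ~ N(0, vw)
# Initialized like the package filter: x_{1|1} = 0, var_{1|1} = q.
kalman_oracle <- function(r, s, I, rho, alpha, q, g0, g1, vv, d0, d1, vw) {
  K <- length(r)
  xp <- vp <- xf <- vf <- numeric(K)
  xf[1] <- 0; vf[1] <- q; xp[1] <- 0; vp[1] <- q
  for (k in 2:K) {
    xp[k] <- rho * xf[k - 1] + alpha * I[k]
    vp[k] <- rho^2 * vf[k - 1] + q
    # sequential scalar updates for the two channels
    x <- xp[k]; v <- vp[k]
    kg <- v * g1 / (g1^2 * v + vv)
    x <- x + kg * (r[k] - g0 - g1 * x); v <- (1 - kg * g1) * v
    kg <- v * d1 / (d1^2 * v + vw)
    x <- x + kg * (s[k] - d0 - d1 * x); v <- (1 - kg * d1) * v
    xf[k] <- x; vf[k] <- v
  }
  xs <- xf; vs <- vf; A <- numeric(K)
  for (k in (K - 1):1) {
    A[k] <- rho * vf[k] / vp[k + 1]
    xs[k] <- xf[k] + A[k] * (xs[k + 1] - xp[k + 1])
    vs[k] <- vf[k] + A[k]^2 * (vs[k + 1] - vp[k + 1])
  }
  list(x_pred = xp, var_pred = vp, x_filt = xf, var_filt = vf,
       x_smooth = xs, var_smooth = vs, A = A)
}

# Exact single-step posterior for one scalar Gaussian prior and two scalar
# Gaussian observations (information form).
kalman_two_obs_update <- function(x_pred, var_pred, r, s, g0, g1, vv, d0, d1, vw) {
  prec <- 1 / var_pred + g1^2 / vv + d1^2 / vw
  mean <- (x_pred / var_pred + g1 * (r - g0) / vv + d1 * (s - d0) / vw) / prec
  list(mean = mean, var = 1 / prec)
}

# Synthetic Bateman-shaped SCR bump (rise tau0, decay tau1), unit peak.
bateman_bump <- function(n, onset, rate = 4, tau0 = 0.7, tau1 = 2.0, amp = 1) {
  t <- (seq_len(n) - onset) / rate
  b <- ifelse(t > 0, exp(-t / tau1) - exp(-t / tau0), 0)
  amp * b / max(b)
}

# Uninformative-channel parameter set: binary and point-process channels
# carry no state information (beta1 = 0, eta = 0), leaving the two Gaussian
# channels only.
gaussian_only_params <- function(rho = 0.95, alpha = 0.3, var_eps = 0.05,
                                 g = c(0.35, 0.4, 0.002),
                                 d = c(-0.7, 0.2, 0.003)) {
  suppressWarnings(model_params(
    rho = rho, alpha = alpha, beta0 = -4, beta1 = 0,
    gamma0 = g[1], gamma1 = g[2], var_v = g[3],
    delta0 = d[1], delta1 = d[2], var_w = d[3],
    var_eps = var_eps,
    hdig = hdig_params(c(0.9, 0, 200), eta = 0)
  ))
}

# Shared medium-size simulated dataset (built once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_dataset(K = 2000, seed = 101)
    cache
  }
})
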