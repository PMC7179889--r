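#' EM configuration
#'
#' @param tolerance Mean absolute parameter change declaring convergence.
#' @param max_iter Maximum EM iterations.
#' @param beta_mode \code{"empirical"} (beta1 = 1, beta0 from the event rate,
#'   held fixed) or \code{"taylor"} (both coefficients re-estimated each
#'   M-step from Taylor-approximated score equations).
#' @param p0_mode \code{"mean_of_m"} (event rate estimated from the data) or
#'   \code{"given"} (use \code{p0}).
#' @param p0 Baseline SCR probability when \code{p0_mode = "given"}.
#' @param eta_grid Candidate arousal-coupling values for [select_eta()];
#'   negative (arousal speeds the heart).
#' @param overfit_gate Threshold on \code{|var_v - var_w|} (standardized
#'   channels) below which updating would constitute overfitting.
#' @param use_gate Apply the overfit gate / early stopping (intended for
#'   experimental recordings with standardized channels).
#' @param enforce_alpha_nonneg Clamp the stimulus gain at zero if its
#'   unconstrained update is negative.
#' @param standardize_continuous Divide r and s by their sample standard
#'   deviations before fitting.
#' @param ks_slack Relative slack on the 95% KS bound when selecting eta.
#' @return A list of class \code{em_config}.
#' @export
em_config <- function(tolerance = 1e-5, max_iter = 200,
                      beta_mode = c("empirical", "taylor"),
                      p0_mode = c("mean_of_m", "given"), p0 = NULL,
                      eta_grid = -10^-(6:1),
                      overfit_gate = 0.1, use_gate = FALSE,
                      enforce_alpha_nonneg = FALSE,
                      standardize_continuous = FALSE,
                      ks_slack = 0.1) {
  stopifnot(tolerance > 0, all(eta_grid < 0))
  structure(list(tolerance = tolerance, max_iter = max_iter,
                 beta_mode = match.arg(beta_mode),
                 p0_mode = match.arg(p0_mode), p0 = p0,
                 eta_grid = sort(eta_grid, decreasing = TRUE),
                 overfit_gate = overfit_gate, use_gate = use_gate,
                 enforce_alpha_nonneg = enforce_alpha_nonneg,
                 standardize_continuous = standardize_continuous,
                 ks_slack = ks_slack),
            class = "em_config")
}

# Smoothed sufficient statistics: U_k = x_{k|K}^2 + var_{k|K},
# U_{k,k+1} = x_{k|K} x_{k+1|K} + A_k var_{k+1|K}.
suff_stats <- function(traj) {
  if (!"x_smooth" %in% names(traj)) stop("trajectory must be smoothed")
  K <- nrow(traj)
  U <- traj$x_smooth^2 + traj$var_smooth
  U12 <- traj$x_smooth[-K] * traj$x_smooth[-1] +
    traj$A[-K] * traj$var_smooth[-1]
  list(U = U, U12 = U12, x = traj$x_smooth, v = traj$var_smooth, K = K)
}

#' M-step for the state parameters (rho, alpha, var_eps)
#'
#' Solves the 2x2 normal equations built from the smoothed second moments,
#' then the closed-form process-noise update. With no stimulus impulses the
#' alpha column is degenerate and alpha is fixed at 0. Under the
#' non-negativity constraint a negative alpha solution is clamped to 0 and
#' rho re-solved from the reduced equation.
#'
#' @param stats Smoothed sufficient statistics (internal; from a smoothed
#'   trajectory).
#' @param I Stimulus indicator vector.
#' @param enforce_alpha_nonneg Clamp negative alpha at zero.
#' @return List with \code{rho}, \code{alpha}, \code{var_eps}.
#' @export
mstep_state <- function(stats, I, enforce_alpha_nonneg = FALSE) {
  K <- stats$K
  x <- stats$x; U <- stats$U; U12 <- stats$U12
  I <- as.numeric(I)
  sU <- sum(U[-K]); sU12 <- sum(U12)
  sIx_prev <- sum(I[-1] * x[-K])
  sI2 <- sum(I^2)
  sIx <- sum(I[-1] * x[-1])
  solve_rho_only <- function() sU12 / sU
  if (sI2 == 0) {
    rho <- solve_rho_only(); alpha <- 0
  } else {
    A <- matrix(c(sU, sIx_prev, sIx_prev, sI2), 2)
    if (abs(det(A)) < 1e-300) stop("singular state normal equations")
    sol <- solve(A, c(sU12, sIx))
    rho <- sol[1]; alpha <- sol[2]
    if (enforce_alpha_nonneg && alpha < 0) {
      alpha <- 0; rho <- solve_rho_only()
    }
  }
  var_eps <- (sum(U[-1]) - 2 * rho * sU12 + rho^2 * sU -
                2 * alpha * sIx + 2 * alpha * rho * sIx_prev +
                alpha^2 * sI2) / K
  list(rho = rho, alpha = alpha, var_eps = max(var_eps, 1e-12))
}

#' M-step for a linear-Gaussian observation channel
#'
#' Closed-form intercept/slope from the smoothed moments and the
#' corresponding variance update; applied identically to the phasic-derived
#' and tonic channels.
#'
#' @param stats Smoothed sufficient statistics.
#' @param y Observed channel series.
#' @return List with \code{intercept}, \code{slope}, \code{var}.
#' @export
mstep_linear_channel <- function(stats, y) {
  K <- stats$K
  sx <- sum(stats$x); sU <- sum(stats$U)
  A <- matrix(c(K, sx, sx, sU), 2)
  if (abs(det(A)) < 1e-300 || sU - sx^2 / K <= 0)
    stop("singular channel normal equations (constant smoothed state)")
  sol <- solve(A, c(sum(y), sum(y * stats$x)))
  i0 <- sol[1]; i1 <- sol[2]
  v <- (sum(y^2) + K * i0^2 + i1^2 * sU - 2 * i0 * sum(y) -
          2 * i1 * sum(stats$x * y) + 2 * i0 * i1 * sx) / K
  list(intercept = i0, slope = i1, var = max(v, 0))
}

#' Empirical beta strategy
#'
#' Sets \code{beta1 = 1} and \code{beta0 = log(p0 / (1 - p0))}, with
#' \code{p0} the chance (or empirical average) probability of an SCR event;
#' held fixed across EM iterations.
#'
#' @param m Binary event series.
#' @param p0 Baseline probability; default \code{mean(m)}.
#' @return List with \code{beta0}, \code{beta1 = 1}.
#' @export
beta_empirical <- function(m, p0 = NULL) {
  if (is.null(p0)) p0 <- mean(m)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("baseline event probability must lie strictly in (0, 1); observed ", p0)
  list(beta0 = stats::qlogis(p0), beta1 = 1)
}

#' Taylor-approximated beta M-step
#'
#' Jointly solves the two second-order-approximate score equations for the
#' logit intercept and slope, using a damped Newton root finder started from
#' the previous iterate. On failure the previous values are kept with a
#' warning (this mode is known to be convergence-sensitive).
#'
#' @param m Binary event series.
#' @param x_smooth,var_smooth Smoothed state means and variances.
#' @param start Numeric c(beta0, beta1) starting point.
#' @return List with \code{beta0}, \code{beta1}, \code{converged}.
#' @export
beta_taylor <- function(m, x_smooth, var_smooth, start = c(0, 1)) {
  if (all(m == 0) || all(m == 1))
    stop("degenerate event series (all 0 or all 1)")
  score <- function(b) {
    p <- stats::plogis(b[1] + b[2] * x_smooth)
    f1 <- sum(m - p - 0.5 * b[2]^2 * var_smooth * p * (1 - p) * (1 - 2 * p))
    f2 <- sum(m * x_smooth - x_smooth * p -
                0.5 * b[2] * var_smooth * p * (1 - p) *
                (2 + b[2] * x_smooth * (1 - 2 * p)))
    c(f1, f2)
  }
  b <- start
  ok <- FALSE
  for (it in 1:100) {
    f <- score(b)
    if (sqrt(sum(f^2)) < 1e-8) { ok <- TRUE; break }
    # numeric Jacobian
    h <- 1e-6 * pmax(abs(b), 1)
    Jc <- cbind((score(b + c(h[1], 0)) - score(b - c(h[1], 0))) / (2 * h[1]),
                (score(b + c(0, h[2])) - score(b - c(0, h[2]))) / (2 * h[2]))
    step <- tryCatch(solve(Jc, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    d <- 1
    while (d > 1e-4 && sqrt(sum(score(b - d * step)^2)) > sqrt(sum(f^2)))
      d <- d / 2
    b_new <- b - d * step
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; ok <- sqrt(sum(score(b)^2)) < 1e-6; break }
    b <- b_new
  }
  if (!ok && sqrt(sum(score(b)^2)) >= 1e-6) {
    warning("beta Taylor M-step root finder did not converge; keeping previous values")
    return(list(beta0 = start[1], beta1 = start[2], converged = FALSE))
  }
  list(beta0 = b[1], beta1 = b[2], converged = TRUE)
}

# Expected Bernoulli-channel log likelihood (second-order approximation at
# the smoothed mean); logged per EM iteration.
q1bar <- function(traj, m, beta0, beta1) {
  e <- beta0 + beta1 * traj$x_smooth
  p <- stats::plogis(e)
  sum(m * e - log1p(exp(pmin(e, 30))) - pmax(e - 30, 0) -
        0.5 * beta1^2 * traj$var_smooth * p * (1 - p))
}

#' Approximate expected point-process log likelihood
#'
#' The heartbeat-channel contribution to the expected complete-data log
#' likelihood, approximated to second order around the smoothed state: the
#' plug-in Bernoulli-bin log likelihood plus a curvature correction scaled by
#' the smoothed variance.
#'
#' @param traj A smoothed \code{arousal_traj}.
#' @param heartbeats A [heartbeat_series()].
#' @param params An \code{arousal_params} object (theta, shape, eta used).
#' @return Scalar value.
#' @export
q2bar <- function(traj, heartbeats, params) {
  if (!"x_smooth" %in% names(traj)) stop("trajectory must be smoothed")
  pp <- pp_precompute(heartbeats, params$hdig, K = nrow(traj))
  q2bar_pp(traj, pp, params$hdig)
}

q2bar_pp <- function(traj, pp, hdig) {
  if (!"x_smooth" %in% names(traj)) stop("trajectory must be smoothed")
  ok <- pp$valid
  kk <- row(pp$w)[ok]
  mu <- pp$mu_hat[ok] + hdig$eta * traj$x_smooth[kk]
  mu <- pmax(mu, 1e-6)
  d <- cif_derivs(pp$w[ok], mu, hdig$shape)
  lam <- pmax(d$lambda, 1e-300)
  l1 <- hdig$eta * d$dlambda
  l2 <- hdig$eta^2 * d$d2lambda
  n <- pp$n[ok]
  lamD <- pmin(lam * pp$delta, 1 - 1e-12)
  v <- traj$var_smooth[kk]
  sum(n * log(lamD) - lam * pp$delta +
        0.5 * (l2 / lam * (n - lam * pp$delta) - n * (l1 / lam)^2) * v)
}

#' Run the full EM loop
#'
#' Alternates state estimation (forward filter + fixed-interval smoother)
#' with closed-form M-steps for the state and the two Gaussian channels, and
#' the configured beta strategy. The HDIG parameters (theta, q, eta) are held
#' fixed (two-step strategy: theta by offline maximum likelihood, eta chosen
#' by [select_eta()]).
#'
#' @param obs An [observation_set()].
#' @param heartbeats A [heartbeat_series()] or NULL.
#' @param stimuli A [stimulus_train()] or NULL.
#' @param hdig An [hdig_params()] object (fixed during EM).
#' @param config An [em_config()].
#' @param init Optional \code{arousal_params} to start from.
#' @return An object of class \code{em_result}: \code{params} (final),
#'   \code{trajectory} (final smoothed), \code{q1bar}, \code{q2bar},
#'   \code{q_gauss} (expected log likelihoods per iteration: Bernoulli
#'   channel, heartbeat point process, state + Gaussian channels),
#'   \code{iterations}, \code{stop_reason} (one of
#'   \code{converged}, \code{overfit_stop}, \code{max_iter}), \code{scale}
#'   (standardization divisors applied to r and s), and \code{trace} (per
#'   iteration parameter values).
#' @export
run_em <- function(obs, heartbeats = NULL, stimuli = NULL, hdig,
                   config = em_config(), init = NULL) {
  scale_r <- scale_s <- 1
  if (config$standardize_continuous) {
    scale_r <- stats::sd(obs$r); scale_s <- stats::sd(obs$s)
    obs <- observation_set(obs$m, obs$r / scale_r, obs$s / scale_s,
                           rate = obs$rate)
  }
  K <- obs$K
  beta <- if (!is.null(init)) {
    list(beta0 = init$beta0, beta1 = init$beta1)
  } else if (config$beta_mode == "empirical") {
    beta_empirical(obs$m, p0 = if (config$p0_mode == "given") config$p0 else NULL)
  } else {
    p0 <- mean(obs$m)
    if (p0 <= 0 || p0 >= 1) stop("degenerate event series")
    list(beta0 = stats::qlogis(p0), beta1 = 1)
  }
  params <- if (!is.null(init)) init else model_params(
    rho = 0.99, alpha = 0.01,
    beta0 = beta$beta0, beta1 = beta$beta1,
    gamma0 = mean(obs$r), gamma1 = 1, var_v = max(stats::var(obs$r), 1e-6),
    delta0 = mean(obs$s), delta1 = 1, var_w = max(stats::var(obs$s), 1e-6),
    var_eps = 0.01, hdig = hdig)
  params$hdig <- hdig

  pp <- if (!is.null(heartbeats)) pp_precompute(heartbeats, hdig, K = K) else NULL

  par_vec <- function(p) c(p$rho, p$alpha, p$beta0, p$beta1, p$gamma0,
                           p$gamma1, p$var_v, p$delta0, p$delta1, p$var_w,
                           p$var_eps)
  # expected log likelihood of the state recursion and Gaussian channels
  q_gauss <- function(st, p, I) {
    x <- st$x; U <- st$U; K <- st$K
    ss_state <- sum(U[-1]) - 2 * p$rho * sum(st$U12) + p$rho^2 * sum(U[-K]) -
      2 * p$alpha * sum(I[-1] * x[-1]) +
      2 * p$alpha * p$rho * sum(I[-1] * x[-K]) + p$alpha^2 * sum(I^2)
    ss_ch <- function(y, i0, i1) sum((y - i0 - i1 * x)^2) + i1^2 * sum(st$v)
    -(K - 1) / 2 * log(2 * pi * p$var_eps) - ss_state / (2 * p$var_eps) -
      K / 2 * log(2 * pi * p$var_v) -
      ss_ch(obs$r, p$gamma0, p$gamma1) / (2 * p$var_v) -
      K / 2 * log(2 * pi * p$var_w) -
      ss_ch(obs$s, p$delta0, p$delta1) / (2 * p$var_w)
  }
  q1 <- q2 <- qg <- numeric(0)
  trace <- list()
  stop_reason <- "max_iter"
  traj <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    traj <- sa_smooth(forward_filter(obs, heartbeats, stimuli, params, pp = pp))
    st <- suff_stats(traj)
    I <- if (is.null(stimuli)) integer(K) else stimuli$I
    q1 <- c(q1, q1bar(traj, obs$m, params$beta0, params$beta1))
    q2 <- c(q2, if (!is.null(pp)) q2bar_pp(traj, pp, hdig) else NA_real_)
    qg <- c(qg, q_gauss(st, params, I))
    up_state <- mstep_state(st, I, config$enforce_alpha_nonneg)
    up_r <- mstep_linear_channel(st, obs$r)
    up_s <- mstep_linear_channel(st, obs$s)
    up_beta <- if (config$beta_mode == "taylor") {
      bt <- tryCatch(beta_taylor(obs$m, traj$x_smooth, traj$var_smooth,
                                 start = c(params$beta0, params$beta1)),
                     warning = function(w) list(beta0 = params$beta0,
                                                beta1 = params$beta1))
      list(beta0 = bt$beta0, beta1 = bt$beta1)
    } else beta

    if (config$use_gate &&
        abs(up_r$var - up_s$var) < config$overfit_gate) {
      stop_reason <- "overfit_stop"
      break  # parameters stay at the last pre-gate iterate
    }

    new <- params
    new$rho <- up_state$rho; new$alpha <- up_state$alpha
    new$var_eps <- up_state$var_eps
    new$gamma0 <- up_r$intercept; new$gamma1 <- up_r$slope
    new$var_v <- max(up_r$var, 1e-10)
    new$delta0 <- up_s$intercept; new$delta1 <- up_s$slope
    new$var_w <- max(up_s$var, 1e-10)
    new$beta0 <- up_beta$beta0; new$beta1 <- up_beta$beta1

    delta_par <- mean(abs(par_vec(new) - par_vec(params)))
    params <- new
    trace[[iter]] <- par_vec(params)
    if (delta_par < config$tolerance) { stop_reason <- "converged"; break }
    if (iter >= config$max_iter) { stop_reason <- "max_iter"; break }
  }
  # final E-step under the final parameters
  traj <- sa_smooth(forward_filter(obs, heartbeats, stimuli, params, pp = pp))
  tr <- if (length(trace)) do.call(rbind, trace) else matrix(numeric(0), 0, 11)
  colnames(tr) <- c("rho", "alpha", "beta0", "beta1", "gamma0", "gamma1",
                    "var_v", "delta0", "delta1", "var_w", "var_eps")
  structure(list(params = params, trajectory = traj,
                 q1bar = q1, q2bar = q2, q_gauss = qg, iterations = iter,
                 stop_reason = stop_reason,
                 scale = c(r = scale_r, s = scale_s),
                 trace = tr),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("EM fit: %d iteration(s), stop_reason = %s\n",
              x$iterations, x$stop_reason))
  print(x$params)
  invisible(x)
}

#' Select the arousal-heartbeat coupling from a candidate grid
#'
#' Runs the full EM at every candidate coupling value, evaluates the
#' approximate expected point-process log likelihood and the post-fit
#' time-rescaling KS distance (with the arousal-coupled intensity at the
#' smoothed state), and returns the candidate maximizing the likelihood among
#' those whose KS distance stays within (a small slack of) the 95% bound.
#' Ties within 1e-6 go to the smallest coupling magnitude; if no candidate
#' satisfies the KS constraint the one with the smallest KS distance is
#' returned, flagged.
#'
#' @inheritParams run_em
#' @param hdig_base An [hdig_params()] with theta/shape fixed (its eta is
#'   replaced by each grid value).
#' @return List with \code{eta_best}, \code{report} (data.frame of eta,
#'   q2bar, ks_distance, ks_bound, admissible), \code{fit} (the
#'   \code{em_result} at the selected eta) and \code{flagged}.
#' @export
select_eta <- function(obs, heartbeats, stimuli, hdig_base,
                       config = em_config()) {
  grid <- config$eta_grid
  fits <- vector("list", length(grid))
  q2v <- ks <- bound <- numeric(length(grid))
  for (i in seq_along(grid)) {
    h <- hdig_params(c(hdig_base$theta, hdig_base$shape), eta = grid[i])
    fits[[i]] <- run_em(obs, heartbeats, stimuli, h, config)
    q2v[i] <- utils::tail(fits[[i]]$q2bar, 1)
    z <- hdig_rescaled(heartbeats$beat_times, h,
                       x = fits[[i]]$trajectory$x_smooth, ts = heartbeats$ts)
    kg <- ks_goodness(z = z)
    ks[i] <- kg$ks_distance; bound[i] <- kg$bounds_95
  }
  adm <- ks <= bound * (1 + config$ks_slack)
  flagged <- !any(adm)
  if (flagged) {
    best <- which.min(ks)
  } else {
    cand <- which(adm)
    top <- max(q2v[cand])
    near <- cand[q2v[cand] >= top - 1e-6]
    best <- near[which.min(abs(grid[near]))]
  }
  list(eta_best = grid[best],
       report = data.frame(eta = grid, q2bar = q2v, ks_distance = ks,
                           ks_bound = bound, admissible = adm),
       fit = fits[[best]], flagged = flagged)
}
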