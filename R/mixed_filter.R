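#' @name mixed_filter
#' @title Gaussian-approximate mixed-observation filter and smoother
#' @description
#' The forward filter propagates a Gaussian approximation to the posterior of
#' the latent arousal state given four simultaneous observation streams: a
#' Bernoulli SCR-event series (logit link), two linear-Gaussian
#' skin-conductance channels, and heartbeat point-process bins with an HDIG
#' conditional intensity. The update step solves a one-dimensional fixed-point
#' equation by damped Newton iteration (the filtered mean appears on both
#' sides through the event probability and the intensity). Fixed-interval
#' smoothing is the standard backward recursion.
NULL

#' One-step state prediction
#'
#' @param x_prev,var_prev Filtered mean and variance at the previous sample.
#' @param params An \code{arousal_params} object.
#' @param I_k Stimulus indicator at the current sample (0/1).
#' @return List with \code{x_pred}, \code{var_pred}.
#' @export
sa_predict <- function(x_prev, var_prev, params, I_k = 0) {
  if (var_prev < 0) stop("var_prev must be >= 0")
  x_pred <- params$rho * x_prev + params$alpha * I_k
  var_pred <- params$rho^2 * var_prev + params$var_eps
  if (var_pred <= 0) warning("degenerate prediction variance (<= 0)")
  list(x_pred = x_pred, var_pred = var_pred)
}

# Precompute the per-bin point-process geometry that does not depend on the
# state: waiting time since the last beat at each bin center, the
# history-based part of the HDIG mean, the beat indicator, and a validity
# mask (bins before q completed RR intervals are excluded from likelihood
# sums). Returned matrices are K x J.
pp_precompute <- function(heartbeats, hdig, K = heartbeats$K) {
  J <- heartbeats$J; delta <- heartbeats$delta; ts <- heartbeats$ts
  if (heartbeats$K < K) stop("heartbeat series shorter than observation series")
  bt <- heartbeats$beat_times
  rr <- heartbeats$rr
  q <- hdig$q
  centers <- (rep(seq_len(K) - 1L, each = J) * ts) + (rep(seq_len(J), K) - 0.5) * delta
  l <- findInterval(centers, bt)          # index of last beat at/before center
  valid <- l >= q + 1                      # q completed intervals available
  w <- centers - ifelse(l >= 1, bt[pmax(l, 1)], NA_real_)
  mu_hat <- rep(NA_real_, length(centers))
  if (any(valid)) {
    lv <- l[valid]
    mh <- rep(hdig$theta[1], length(lv))
    if (q > 0) for (i in seq_len(q)) mh <- mh + hdig$theta[i + 1] * rr[lv - i]
    mu_hat[valid] <- mh
  }
  byrow_mat <- function(v) matrix(v, nrow = K, ncol = J, byrow = TRUE)
  list(
    w = byrow_mat(w), mu_hat = byrow_mat(mu_hat),
    n = heartbeats$n[seq_len(K), , drop = FALSE],
    valid = byrow_mat(valid), delta = delta, J = J
  )
}

# Point-process contributions at state value x for sample k.
# Returns the score term sum_j (dlambda/dx / lambda)(n - lambda Delta), its
# x-derivative, and the Fisher-type curvature term of the variance update.
pp_terms <- function(x, ppk, hdig) {
  ok <- ppk$valid
  if (!any(ok) || hdig$eta == 0)
    return(list(score = 0, dscore = 0, curv = 0))
  mu <- ppk$mu_hat[ok] + hdig$eta * x
  bad <- mu <= 1e-6
  if (any(bad)) { mu[bad] <- 1e-6 }
  d <- cif_derivs(ppk$w[ok], mu, hdig$shape)
  lam <- pmax(d$lambda, 1e-300)
  l1 <- hdig$eta * d$dlambda
  l2 <- hdig$eta^2 * d$d2lambda
  n <- ppk$n[ok]
  resid <- n - lam * ppk$delta
  score <- sum(l1 / lam * resid)
  dscore <- sum((l2 / lam - (l1 / lam)^2) * resid - (l1^2 / lam) * ppk$delta)
  curv <- sum(l2 / lam * resid - n * (l1 / lam)^2)
  list(score = score, dscore = dscore, curv = curv)
}

#' Measurement update via damped Newton iteration
#'
#' Solves the fixed-point equation for the filtered mean (the event
#' probability and the heartbeat intensity are evaluated at the solution) and
#' forms the filtered variance from the local curvature of all four channels.
#'
#' @param x_pred,var_pred Predicted mean and variance.
#' @param m_k Binary SCR event (0/1).
#' @param r_k,s_k Continuous observations (phasic-derived, tonic).
#' @param ppk Per-sample point-process terms from the internal precomputation,
#'   or NULL to omit the heartbeat channel.
#' @param params An \code{arousal_params} object.
#' @param tol Newton step-size tolerance.
#' @param max_iter Maximum Newton iterations before bisection fallback.
#' @return List with \code{x_filt}, \code{var_filt}, \code{p_filt},
#'   \code{gain} (the scalar c_k), \code{residual} (fixed-point residual) and
#'   \code{newton_iter}.
#' @export
sa_update <- function(x_pred, var_pred, m_k, r_k, s_k, ppk, params,
                      tol = 1e-8, max_iter = 50) {
  if (var_pred <= 0) stop("var_pred must be > 0")
  vv <- params$var_v; vw <- params$var_w
  g1 <- params$gamma1; d1 <- params$delta1
  b0 <- params$beta0; b1 <- params$beta1
  ck <- var_pred / (vv * vw + var_pred * (g1^2 * vw + d1^2 * vv))
  Pg <- ck * vv * vw  # Gaussian-channel posterior variance
  # Gaussian innovations are evaluated at the predicted mean (fixed in x)
  G <- g1 / vv * (r_k - params$gamma0 - g1 * x_pred) +
       d1 / vw * (s_k - params$delta0 - d1 * x_pred)
  hdig <- params$hdig
  use_pp <- !is.null(ppk) && hdig$eta != 0

  fres <- function(x) {
    p <- stats::plogis(b0 + b1 * x)
    sc <- if (use_pp) pp_terms(x, ppk, hdig)$score else 0
    x - x_pred - Pg * (b1 * (m_k - p) + G + sc)
  }

  eval_at <- function(x) {
    p <- stats::plogis(b0 + b1 * x)
    pp <- if (use_pp) pp_terms(x, ppk, hdig) else list(score = 0, dscore = 0, curv = 0)
    list(p = p, pp = pp,
         f = x - x_pred - Pg * (b1 * (m_k - p) + G + pp$score),
         fp = 1 + Pg * (b1^2 * p * (1 - p)) - Pg * pp$dscore)
  }
  x <- x_pred
  cur <- eval_at(x)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    step <- cur$f / cur$fp
    d <- 1
    x_new <- x - step
    nxt <- eval_at(x_new)
    # damp on divergence
    while (abs(nxt$f) > abs(cur$f) && d > 1e-4) {
      d <- d / 2
      x_new <- x - d * step
      nxt <- eval_at(x_new)
    }
    if (abs(x_new - x) < tol) { x <- x_new; cur <- nxt; converged <- TRUE; break }
    x <- x_new; cur <- nxt
    if (iter >= max_iter) break
  }
  if (!converged && abs(fres(x)) > 1e-8) {
    # bisection fallback on the fixed-point residual
    lo <- x_pred - 50; hi <- x_pred + 50
    flo <- fres(lo); fhi <- fres(hi)
    if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
      for (i in 1:200) {
        mid <- (lo + hi) / 2; fm <- fres(mid)
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        if (hi - lo < 1e-12) break
      }
      x <- (lo + hi) / 2
    } else {
      stop("Newton update failed to converge and no bisection bracket found")
    }
  }

  p <- cur$p
  pc <- min(max(p, 1e-10), 1 - 1e-10)  # clip inside the information term
  prec <- 1 / var_pred + b1^2 * pc * (1 - pc) + g1^2 / vv + d1^2 / vw - cur$pp$curv
  if (prec <= 0) stop("filtered variance nonpositive: model inconsistency")
  list(x_filt = x, var_filt = 1 / prec, p_filt = p, gain = ck,
       residual = cur$f, newton_iter = iter)
}

#' Forward filter over a full recording
#'
#' Runs predict/update sequentially over all samples. Initialization:
#' \code{x_{1|1} = 0}, \code{var_{1|1} = var_eps} (the state is taken as
#' approximately zero at the very beginning).
#'
#' @param obs An [observation_set()].
#' @param heartbeats A [heartbeat_series()], or NULL to omit the heartbeat
#'   channel.
#' @param stimuli A [stimulus_train()], or NULL for no stimulus input.
#' @param params An \code{arousal_params} object.
#' @param pp Optional precomputed point-process geometry (internal reuse
#'   across EM iterations).
#' @return An object of class \code{arousal_traj}: a data.frame with columns
#'   \code{k, time_s, x_pred, var_pred, x_filt, var_filt, p_filt, gain},
#'   carrying attributes used by [sa_smooth()].
#' @export
forward_filter <- function(obs, heartbeats = NULL, stimuli = NULL, params,
                           pp = NULL) {
  K <- obs$K
  I <- if (is.null(stimuli)) integer(K) else stimuli$I
  if (length(I) != K) stop("stimulus indicator length mismatch")
  if (!is.null(heartbeats) && is.null(pp) && params$hdig$eta != 0)
    pp <- pp_precompute(heartbeats, params$hdig, K = K)
  x_pred <- var_pred <- x_filt <- var_filt <- p_filt <- gain <- resid <- numeric(K)
  x_filt[1] <- 0
  var_filt[1] <- params$var_eps
  x_pred[1] <- 0; var_pred[1] <- params$var_eps
  p_filt[1] <- stats::plogis(params$beta0 + params$beta1 * x_filt[1])
  gain[1] <- NA_real_
  if (K >= 2) for (k in 2:K) {
    pr <- sa_predict(x_filt[k - 1], var_filt[k - 1], params, I[k])
    ppk <- if (!is.null(pp))
      list(w = pp$w[k, ], mu_hat = pp$mu_hat[k, ], n = pp$n[k, ],
           valid = pp$valid[k, ], delta = pp$delta) else NULL
    up <- tryCatch(
      sa_update(pr$x_pred, pr$var_pred, obs$m[k], obs$r[k], obs$s[k], ppk, params),
      error = function(e) stop("update failed at k = ", k, ": ", conditionMessage(e))
    )
    x_pred[k] <- pr$x_pred; var_pred[k] <- pr$var_pred
    x_filt[k] <- up$x_filt; var_filt[k] <- up$var_filt
    p_filt[k] <- up$p_filt; gain[k] <- up$gain; resid[k] <- up$residual
  }
  out <- data.frame(k = seq_len(K), time_s = (seq_len(K) - 1) / obs$rate,
                    x_pred = x_pred, var_pred = var_pred,
                    x_filt = x_filt, var_filt = var_filt,
                    p_filt = p_filt, gain = gain)
  attr(out, "residuals") <- resid
  attr(out, "params") <- params
  class(out) <- c("arousal_traj", "data.frame")
  out
}

#' Fixed-interval smoother
#'
#' Backward recursion combining each filtered estimate with the smoothed
#' estimate one step ahead: \code{A_k = rho var_filt_k / var_pred_{k+1}}.
#'
#' @param traj An \code{arousal_traj} from [forward_filter()].
#' @param params An \code{arousal_params} object (defaults to the parameters
#'   stored in the trajectory).
#' @return The trajectory with columns \code{x_smooth, var_smooth, A} added.
#' @export
sa_smooth <- function(traj, params = attr(traj, "params")) {
  K <- nrow(traj)
  x_s <- numeric(K); v_s <- numeric(K); A <- rep(NA_real_, K)
  x_s[K] <- traj$x_filt[K]; v_s[K] <- traj$var_filt[K]
  if (K >= 2) for (k in (K - 1):1) {
    vp <- traj$var_pred[k + 1]
    if (vp <= 0) stop("zero prediction variance at k = ", k + 1)
    A[k] <- params$rho * traj$var_filt[k] / vp
    x_s[k] <- traj$x_filt[k] + A[k] * (x_s[k + 1] - traj$x_pred[k + 1])
    v_s[k] <- traj$var_filt[k] + A[k]^2 * (v_s[k + 1] - vp)
  }
  traj$x_smooth <- x_s
  traj$var_smooth <- v_s
  traj$A <- A
  traj
}

#' @export
print.arousal_traj <- function(x, ...) {
  cat(sprintf("arousal_traj: K = %d samples%s\n", nrow(x),
              if ("x_smooth" %in% names(x)) " (smoothed)" else " (filtered only)"))
  cat(sprintf("  x_filt range [%.3f, %.3f]\n", min(x$x_filt), max(x$x_filt)))
  invisible(x)
}
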