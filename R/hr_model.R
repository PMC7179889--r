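#' Heartbeat series: R-peak times, RR intervals and point-process binning
#'
#' Beats are binned into 5 ms bins, grouped into J = ts/delta bins per latent
#' state sample, matching the mixed filter's point-process observation model.
#'
#' @param beat_times Strictly increasing R-peak times in seconds, within
#'   \code{(0, T]}.
#' @param T Total recording duration in seconds; defaults to the last beat.
#' @param delta Point-process bin width in seconds (default 0.005).
#' @param ts Latent-state sampling interval in seconds (default 0.25, i.e. 4 Hz).
#' @return An object of class \code{heartbeat_series} with fields
#'   \code{beat_times}, \code{rr} (RR intervals), \code{T}, \code{delta},
#'   \code{J} (bins per sample), and \code{n} (a K-by-J binary matrix of beat
#'   indicators).
#' @export
heartbeat_series <- function(beat_times, T = NULL, delta = 0.005, ts = 0.25) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing")
  if (is.null(T)) T <- if (length(beat_times)) beat_times[length(beat_times)] else 0
  if (length(beat_times) && (beat_times[1] <= 0 || beat_times[length(beat_times)] > T))
    stop("beat times must lie in (0, T]")
  J <- as.integer(round(ts / delta))
  if (abs(J * delta - ts) > 1e-9) stop("ts must be an integer multiple of delta")
  K <- as.integer(ceiling(T / ts - 1e-9))
  nbins <- K * J
  # half-open bins [t, t + delta); a beat at exactly T falls in the last bin
  idx <- pmin(floor(beat_times / delta) + 1L, nbins)
  if (anyDuplicated(idx))
    stop("two beats fall in one ", delta * 1000, " ms bin: RR interval < bin width, check input")
  n <- matrix(0L, nrow = K, ncol = J)
  if (length(idx)) {
    # idx is a linear bin index over time; map to (sample k, within-sample j)
    k <- (idx - 1L) %/% J + 1L
    j <- (idx - 1L) %% J + 1L
    n[cbind(k, j)] <- 1L
  }
  structure(list(beat_times = beat_times, rr = diff(beat_times),
                 T = T, delta = delta, ts = ts, J = J, K = K, n = n),
            class = "heartbeat_series")
}

#' @export
print.heartbeat_series <- function(x, ...) {
  cat(sprintf("heartbeat_series: %d beats over %.1f s (mean RR %.3f s), %d x %d bins of %g ms\n",
              length(x$beat_times), x$T,
              if (length(x$rr)) mean(x$rr) else NA_real_,
              x$K, x$J, x$delta * 1000))
  invisible(x)
}

#' HDIG mean RR interval given history and arousal
#'
#' @param history The most recent \code{q} RR intervals, most recent first
#'   is NOT assumed: element i multiplies theta_i, i.e. \code{history[1]} is
#'   the latest completed interval.
#' @param hdig An [hdig_params()] object.
#' @param x Arousal state value (default 0).
#' @return Predicted mean interval in seconds: theta0 + sum(theta_i * h_i) +
#'   eta * x.
#' @export
hdig_mean <- function(history, hdig, x = 0) {
  q <- hdig$q
  if (length(history) != q) stop("history must contain exactly q = ", q, " intervals")
  mu <- hdig$theta[1] + if (q > 0) sum(hdig$theta[-1] * history) else 0
  mu + hdig$eta * x
}

#' Inverse-Gaussian density of the next beat time
#'
#' Density of the waiting time \code{t - u_l} since the last beat, with mean
#' \code{mu} and shape \code{shape}.
#'
#' @param t Candidate time (s), \code{t > u_l}.
#' @param u_l Time of the previous beat (s).
#' @param mu Mean interval (s), > 0.
#' @param shape Inverse-Gaussian shape (s), > 0.
#' @return Density value (1/s).
#' @export
hdig_pdf <- function(t, u_l, mu, shape) {
  if (any(t <= u_l)) stop("hdig_pdf requires t > u_l")
  w <- t - u_l
  ig_pdf(w, mu, shape)
}

ig_pdf <- function(w, mu, shape) {
  sqrt(shape / (2 * pi * w^3)) * exp(-shape * (w - mu)^2 / (2 * mu^2 * w))
}

# Closed-form inverse-Gaussian CDF (normal-CDF expression).
ig_cdf <- function(w, mu, shape) {
  sw <- sqrt(shape / w)
  a <- sw * (w / mu - 1)
  b <- -sw * (w / mu + 1)
  stats::pnorm(a) + exp(2 * shape / mu + stats::pnorm(b, log.p = TRUE))
}

# Survival computed without the 1 - CDF cancellation:
# S = Phi(-a) - e^{2 shape/mu} Phi(b), both terms evaluated on the log scale.
ig_surv <- function(w, mu, shape) {
  sw <- sqrt(shape / w)
  a <- sw * (w / mu - 1)
  b <- -sw * (w / mu + 1)
  la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  lb <- 2 * shape / mu + stats::pnorm(b, log.p = TRUE)
  exp(la) * -expm1(lb - la)
}

ig_log_surv <- function(w, mu, shape) {
  sw <- sqrt(shape / w)
  a <- sw * (w / mu - 1)
  b <- -sw * (w / mu + 1)
  la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
  lb <- 2 * shape / mu + stats::pnorm(b, log.p = TRUE)
  la + log1p(-exp(lb - la))
}

#' Conditional intensity of the HDIG heartbeat point process
#'
#' \code{lambda = pdf / (1 - CDF)}, the hazard of a beat at time \code{t}
#' given the last beat at \code{u_l} and the current mean/shape.
#'
#' @inheritParams hdig_pdf
#' @param warn Warn when the survival underflows and is clipped (default TRUE).
#' @return Intensity (1/s).
#' @export
hdig_cif <- function(t, u_l, mu, shape, warn = TRUE) {
  if (any(t <= u_l)) stop("hdig_cif requires t > u_l")
  w <- t - u_l
  surv <- ig_surv(w, mu, shape)
  if (any(surv < 1e-12)) {
    if (warn) warning("survival underflow in hdig_cif; clipped at 1e-12")
    surv <- pmax(surv, 1e-12)
  }
  ig_pdf(w, mu, shape) / surv
}

# CIF and its first and second partial derivatives w.r.t. mu, vectorized
# over w (waiting times). Derivation: with g the IG pdf and F the IG cdf,
#   dlog g/dmu   = shape (w - mu) / mu^3
#   d2log g/dmu2 = shape (2 mu - 3 w) / mu^4
#   dF/dmu       = -(2 shape / mu^2) e^{2 shape/mu} Phi(b),  b = -sqrt(shape/w)(w/mu + 1)
# (the phi terms cancel via e^{2 shape/mu} phi(b) = phi(a)), and
#   d2F/dmu2     = (4 shape/mu^3 + 4 shape^2/mu^4) e^{2 shape/mu} Phi(b)
#                  - 2 shape sqrt(shape w) phi(a) / mu^4,   a = sqrt(shape/w)(w/mu - 1).
cif_derivs <- function(w, mu, shape) {
  g <- ig_pdf(w, mu, shape)
  lg1 <- shape * (w - mu) / mu^3
  lg2 <- shape * (2 * mu - 3 * w) / mu^4
  g1 <- g * lg1
  g2 <- g * (lg1^2 + lg2)

  sw <- sqrt(shape / w)
  a <- sw * (w / mu - 1)
  b <- -sw * (w / mu + 1)
  # E * Phi(b) computed on log scale to dodge overflow of e^{2 shape/mu}
  EPhib <- exp(2 * shape / mu + stats::pnorm(b, log.p = TRUE))
  phia <- stats::dnorm(a)
  F1 <- -(2 * shape / mu^2) * EPhib
  F2 <- (4 * shape / mu^3 + 4 * shape^2 / mu^4) * EPhib -
    2 * shape * sqrt(shape * w) * phia / mu^4

  S <- pmax(ig_surv(w, mu, shape), 1e-12)
  lam <- g / S
  lam1 <- g1 / S + g * F1 / S^2
  lam2 <- g2 / S + 2 * g1 * F1 / S^2 + g * F2 / S^2 + 2 * g * F1^2 / S^3
  list(lambda = lam, dlambda = lam1, d2lambda = lam2, surv = S)
}

#' Fit HDIG parameters by maximum likelihood
#'
#' Maximizes the inverse-Gaussian log likelihood of the observed RR intervals,
#' each with mean \code{theta0 + sum(theta_i h_{l-i})} over the previous
#' \code{q} intervals (arousal coupling held at zero). The first \code{q}
#' intervals serve only as history. Optimization is quasi-Newton (BFGS) with
#' an analytic gradient on an unconstrained parameterisation (log shape),
#' started from a least-squares (method-of-moments) fit.
#'
#' @param rr RR intervals in seconds.
#' @param q Model order (number of history terms).
#' @param grad_tol Gradient-norm tolerance declared at the optimum.
#' @return An [hdig_params()] object with fitted \code{theta} and shape
#'   (\code{eta = 0}), plus attributes \code{logLik} and \code{grad_norm}.
#' @export
fit_hdig_ml <- function(rr, q, grad_tol = 1e-6) {
  rr <- as.numeric(rr)
  L <- length(rr)
  if (L <= q + 2) stop("need more than q + 2 intervals to fit order ", q)
  y <- rr[(q + 1):L]
  X <- cbind(1, if (q > 0) sapply(seq_len(q), function(i) rr[(q + 1 - i):(L - i)]) else NULL)
  X <- matrix(X, nrow = length(y))

  # method-of-moments start: least squares for theta, IG shape from residuals
  th0 <- tryCatch(qr.solve(X, y), error = function(e) c(mean(y), rep(0, q)))
  mu0 <- pmax(X %*% th0, 0.1 * mean(y))
  resvar <- mean((y - mu0)^2)
  shape0 <- max(mean(mu0)^3 / max(resvar, 1e-10), 1)

  negll <- function(par) {
    th <- par[seq_len(q + 1)]
    shape <- exp(par[q + 2])
    mu <- drop(X %*% th)
    if (any(mu <= 1e-8)) return(1e10 + sum(pmax(1e-8 - mu, 0)) * 1e10)
    -sum(0.5 * log(shape) - 0.5 * log(2 * pi * y^3) -
           shape * (y - mu)^2 / (2 * mu^2 * y))
  }
  grad <- function(par) {
    th <- par[seq_len(q + 1)]
    shape <- exp(par[q + 2])
    mu <- drop(X %*% th)
    if (any(mu <= 1e-8)) return(rep(0, q + 2))
    dmu <- shape * (y - mu) / mu^3              # dlogL/dmu per obs
    gth <- -drop(crossprod(X, dmu))
    gsh <- -sum(1 / (2 * shape) - (y - mu)^2 / (2 * mu^2 * y)) * shape
    c(gth, gsh)
  }

  fit <- stats::optim(c(th0, log(shape0)), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # Newton polish: a few damped steps with a numerical Hessian
  par <- fit$par
  for (it in 1:20) {
    gv <- grad(par)
    if (sqrt(sum(gv^2)) < 1e-8) break
    H <- stats::optimHess(par, negll, grad)
    step <- tryCatch(solve(H, gv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    d <- 1
    while (d > 1e-4 && negll(par - d * step) > negll(par)) d <- d / 2
    par_new <- par - d * step
    if (max(abs(par_new - par)) < 1e-14) break
    par <- par_new
  }
  fit <- list(par = par, value = negll(par))
  gn <- sqrt(sum(grad(fit$par)^2))
  if (!is.finite(fit$value) || fit$value >= 1e9)
    stop("HDIG ML fit failed: predicted mean nonpositive at optimum")
  if (gn > max(grad_tol, 1e-6 * abs(fit$value)) && gn > 1e-3)
    stop("HDIG ML fit did not converge (gradient norm ", format(gn), ")")
  out <- hdig_params(c(fit$par[seq_len(q + 1)], exp(fit$par[q + 2])), eta = 0)
  attr(out, "logLik") <- -fit$value
  attr(out, "grad_norm") <- gn
  # observed-information covariance (theta on the natural scale, shape on log)
  attr(out, "vcov") <- tryCatch(
    solve(stats::optimHess(fit$par, negll, grad)),
    error = function(e) NULL)
  out
}

#' Time-rescaling goodness-of-fit (KS distance)
#'
#' Applies the time-rescaling theorem: integrating the conditional intensity
#' across each inter-beat interval yields unit-rate exponential variables if
#' the intensity is correct. The transform \code{1 - exp(-z)} maps them to
#' uniforms, which are compared with uniform quantiles; the KS distance is the
#' maximum vertical distance from the 45-degree diagonal.
#'
#' @param beat_times Beat times in seconds (or NULL when \code{z} is given).
#' @param cif Either a function \code{lambda(t)} returning the intensity at
#'   arbitrary times, or NULL when precomputed rescaled integrals \code{z} are
#'   supplied.
#' @param z Optional precomputed integrals of the intensity across intervals.
#' @param n_grid Subintervals per interval for numerical integration when a
#'   generic \code{cif} function is supplied.
#' @return A list with \code{ks_distance}, \code{rescaled} (sorted uniforms),
#'   \code{model_quantiles}, and \code{bounds_95} = 1.36/sqrt(L).
#' @export
ks_goodness <- function(beat_times = NULL, cif = NULL, z = NULL, n_grid = 200) {
  if (is.null(z)) {
    if (is.null(beat_times) || is.null(cif))
      stop("supply either z or both beat_times and cif")
    if (length(beat_times) < 10) stop("need at least 10 beats")
    L <- length(beat_times) - 1
    z <- vapply(seq_len(L), function(l) {
      t0 <- beat_times[l]; t1 <- beat_times[l + 1]
      tt <- seq(t0, t1, length.out = n_grid + 1)
      mid <- (tt[-1] + tt[-length(tt)]) / 2
      lam <- cif(mid)
      if (any(!is.finite(lam)))
        stop("CIF evaluation failed inside interval ", l)
      sum(lam) * (t1 - t0) / n_grid
    }, numeric(1))
  }
  L <- length(z)
  u <- sort(1 - exp(-z))
  bq <- (seq_len(L) - 0.5) / L
  list(ks_distance = max(abs(u - bq)), rescaled = u, model_quantiles = bq,
       bounds_95 = 1.36 / sqrt(L))
}

# Rescaled integrals for the HDIG model: within an interval the history is
# fixed, and arousal (if any) is piecewise constant on the 4 Hz grid, so
# int lambda dt = -[log S] evaluated piecewise exactly (lambda = -d/dt log S
# for fixed mu). x is the per-sample arousal series (or NULL for eta = 0).
hdig_rescaled <- function(beat_times, hdig, x = NULL, ts = 0.25) {
  q <- hdig$q
  rr <- diff(beat_times)
  L <- length(rr)
  if (L <= q) stop("too few intervals for order ", q)
  z <- numeric(L - q)
  for (l in (q + 1):L) {
    u0 <- beat_times[l]; u1 <- beat_times[l + 1]
    hist <- rr[(l - 1):(l - q)]
    mu_base <- hdig$theta[1] + if (q > 0) sum(hdig$theta[-1] * hist) else 0
    if (is.null(x) || hdig$eta == 0) {
      z[l - q] <- -ig_log_surv(u1 - u0, mu_base, hdig$shape)
    } else {
      # segment boundaries at 4 Hz sample edges between u0 and u1
      first_edge <- ceiling(u0 / ts) * ts
      inner <- if (first_edge < u1) seq(first_edge, u1, by = ts) else numeric(0)
      edges <- unique(c(u0, inner[inner > u0 & inner < u1], u1))
      acc <- 0
      for (sgm in seq_len(length(edges) - 1)) {
        a <- edges[sgm]; b <- edges[sgm + 1]
        if (b <= a) next
        k <- min(floor(a / ts) + 1L, length(x))
        mu <- mu_base + hdig$eta * x[k]
        mu <- max(mu, 1e-6)
        acc <- acc + (ig_log_surv(a - u0, mu, hdig$shape) -
                        ig_log_surv(b - u0, mu, hdig$shape))
        # note: piecewise survival differences; exact for mu constant on [a,b)
      }
      z[l - q] <- acc
    }
  }
  z
}

#' Select the HDIG model order by KS distance
#'
#' Fits every candidate order by maximum likelihood, computes the
#' time-rescaling KS distance for each, and returns the order with the
#' smallest distance (ties broken toward the smaller order). The partial
#' autocorrelation of the RR intervals up to lag 8 is returned for reporting.
#'
#' @param rr RR intervals in seconds.
#' @param q_candidates Candidate orders (default 1..8).
#' @return A list with \code{q_best}, \code{theta_best} (an
#'   \code{hdig_params}), \code{ks_table} (data.frame of order, KS distance,
#'   log-likelihood, fit status), and \code{pacf} (lags 1..8).
#' @export
select_order <- function(rr, q_candidates = 1:8) {
  rr <- as.numeric(rr)
  bt <- c(0, cumsum(rr))
  rows <- lapply(q_candidates, function(q) {
    fit <- tryCatch(fit_hdig_ml(rr, q), error = function(e) e)
    if (inherits(fit, "error"))
      return(list(q = q, ks = NA_real_, ll = NA_real_, fit = NULL,
                  status = conditionMessage(fit)))
    z <- hdig_rescaled(bt, fit)
    ks <- ks_goodness(z = z)$ks_distance
    list(q = q, ks = ks, ll = attr(fit, "logLik"), fit = fit, status = "ok")
  })
  ks <- vapply(rows, `[[`, numeric(1), "ks")
  if (all(is.na(ks))) stop("all candidate HDIG fits failed")
  best <- which(ks <= min(ks, na.rm = TRUE) + 1e-12)[1]  # ties -> smaller q
  list(
    q_best = rows[[best]]$q,
    theta_best = rows[[best]]$fit,
    ks_table = data.frame(
      q = vapply(rows, `[[`, numeric(1), "q"),
      ks_distance = ks,
      logLik = vapply(rows, `[[`, numeric(1), "ll"),
      status = vapply(rows, `[[`, character(1), "status")
    ),
    pacf = drop(stats::pacf(rr, lag.max = 8, plot = FALSE)$acf)
  )
}

#' Detect R peaks in an ECG trace
#'
#' A simple prominence-style detector: band-pass the ECG (5-15 Hz Butterworth,
#' zero phase), then find local maxima exceeding a robust threshold with a
#' minimum 0.3 s separation. Precomputed beat times are the recommended input
#' for analysis; this detector covers clean recordings only (no manual
#' correction).
#'
#' @param ecg A [raw_signal()] in millivolts.
#' @param min_rr Minimum separation between detected peaks (s).
#' @param thresh_mult Threshold as a multiple of the median absolute deviation
#'   of the band-passed signal.
#' @return Numeric vector of R-peak times in seconds.
#' @export
detect_rpeaks <- function(ecg, min_rr = 0.3, thresh_mult = 4) {
  stopifnot(inherits(ecg, "raw_signal"))
  ny <- ecg$rate / 2
  bf <- signal::butter(2, c(5, 15) / ny, type = "pass")
  y <- signal::filtfilt(bf, ecg$values)
  thr <- thresh_mult * stats::mad(y)
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk <- pk[y[pk] > thr]
  if (!length(pk)) return(numeric(0))
  keep <- pk[1]
  for (p in pk[-1]) {
    if ((p - keep[length(keep)]) / ecg$rate >= min_rr) keep <- c(keep, p)
    else if (y[p] > y[keep[length(keep)]]) keep[length(keep)] <- p
  }
  ecg$times[keep]
}
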