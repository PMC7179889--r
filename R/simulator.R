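#' Simulate the latent arousal state
#'
#' First-order autoregression driven by stimulus impulses:
#' \code{x_k = rho x_{k-1} + alpha I_k + eps_k}, \code{eps_k ~ N(0, var_eps)},
#' started from \code{x_0 = 0}.
#'
#' @param K Number of samples.
#' @param params An \code{arousal_params} object.
#' @param I Binary stimulus indicator of length K (default all zero).
#' @param seed Optional integer seed.
#' @return Numeric vector of length K.
#' @export
simulate_state <- function(K, params, I = integer(K), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(I) == K)
  eps <- stats::rnorm(K, 0, sqrt(params$var_eps))
  x <- numeric(K)
  prev <- 0
  for (k in seq_len(K)) {
    x[k] <- params$rho * prev + params$alpha * I[k] + eps[k]
    prev <- x[k]
  }
  x
}

#' Simulate the skin-conductance observation channels
#'
#' Draws the binary SCR-event series from the logit link, and the
#' phasic-derived and tonic channels as affine-Gaussian images of the state.
#'
#' @param x Latent state series.
#' @param params An \code{arousal_params} object.
#' @param seed Optional integer seed.
#' @return A list with binary \code{m}, numeric \code{r} and \code{s}.
#' @export
simulate_sc <- function(x, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(x)
  p <- stats::plogis(params$beta0 + params$beta1 * x)
  m <- stats::rbinom(K, 1, p)
  r <- params$gamma0 + params$gamma1 * x + stats::rnorm(K, 0, sqrt(params$var_v))
  s <- params$delta0 + params$delta1 * x + stats::rnorm(K, 0, sqrt(params$var_w))
  list(m = m, r = r, s = s)
}

# Inverse-Gaussian sampler (Michael-Shucany-Haas transformation).
rinvgauss <- function(n, mu, shape) {
  nu <- stats::rnorm(n)
  y <- nu^2
  xr <- mu + mu^2 * y / (2 * shape) -
    mu / (2 * shape) * sqrt(4 * mu * shape * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + xr), xr, mu^2 / xr)
}

#' Simulate heartbeats from the HDIG generative model
#'
#' Iteratively draws each RR interval from an inverse Gaussian whose mean is
#' \code{theta0 + sum(theta_i h_{l-i+1}) + eta * x(u_l)}, where \code{x(u_l)}
#' is the state sample at the previous beat time (the generative convention:
#' the state is frozen over each interval at its value when the interval
#' starts). Beats are binned at 5 ms.
#'
#' @param x Latent state series at 4 Hz.
#' @param params An \code{arousal_params} object (its \code{hdig} slot is used).
#' @param T Duration in seconds (default \code{length(x) * 0.25}).
#' @param seed Optional integer seed.
#' @param init_history Optional initial q RR intervals; defaults to the
#'   steady-state mean \code{theta0 / (1 - sum(theta_i))} when stable,
#'   otherwise 0.85 s.
#' @return A [heartbeat_series()] object; attribute \code{n_resampled} counts
#'   rejected nonpositive-mean draws.
#' @export
simulate_heartbeats <- function(x, params, T = length(x) * 0.25, seed = NULL,
                                init_history = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hdig <- params$hdig
  q <- hdig$q
  ts <- 0.25
  if (is.null(init_history)) {
    ssum <- if (q > 0) sum(hdig$theta[-1]) else 0
    h0 <- if (ssum < 1 && hdig$theta[1] / (1 - ssum) > 0.2)
      hdig$theta[1] / (1 - ssum) else 0.85
    init_history <- rep(h0, max(q, 1))
  }
  hist <- rev(init_history)[seq_len(max(q, 0))]  # hist[1] = most recent
  t_cur <- 0
  beats <- numeric(0)
  n_resampled <- 0L
  rr_window <- numeric(0)
  repeat {
    k <- min(floor(t_cur / ts) + 1L, length(x))
    mu <- hdig$theta[1] + (if (q > 0) sum(hdig$theta[-1] * hist) else 0) +
      hdig$eta * x[k]
    tries <- 0L
    while (mu <= 0 && tries < 100L) {
      n_resampled <- n_resampled + 1L
      tries <- tries + 1L
      mu <- hdig$theta[1] + (if (q > 0) sum(hdig$theta[-1] * hist) else 0)
    }
    if (mu <= 0) stop("HDIG mean nonpositive; unstable theta")
    h <- rinvgauss(1, mu, hdig$shape)
    t_cur <- t_cur + h
    if (t_cur > T) break
    beats <- c(beats, t_cur)
    if (q > 0) hist <- c(h, hist)[seq_len(q)]
    rr_window <- c(rr_window, h)
    if (length(rr_window) > 20) rr_window <- rr_window[-1]
    if (length(rr_window) == 20 && (mean(rr_window) < 0.2 || mean(rr_window) > 3))
      stop("runaway RR intervals (persistent mean ", round(mean(rr_window), 3),
           " s); unstable theta")
  }
  hb <- heartbeat_series(beats, T = T)
  attr(hb, "n_resampled") <- n_resampled
  hb
}

#' Place stimulus impulses
#'
#' Uniformly without replacement over the sample grid, with a minimum spacing
#' (default 10 s) to mimic trial structure.
#'
#' @param K Number of samples at 4 Hz.
#' @param n_stimuli Number of impulses.
#' @param min_spacing_s Minimum spacing between impulses in seconds.
#' @param rate Sampling rate (Hz).
#' @param seed Optional integer seed.
#' @return A [stimulus_train()] object.
#' @export
place_stimuli <- function(K, n_stimuli = 25, min_spacing_s = 10, rate = 4,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- ceiling(min_spacing_s * rate)
  if (n_stimuli * spacing > K)
    stop("cannot place ", n_stimuli, " stimuli with ", min_spacing_s,
         " s spacing in ", K, " samples")
  picked <- integer(0)
  avail <- seq_len(K)
  for (i in seq_len(n_stimuli)) {
    if (!length(avail)) stop("ran out of admissible stimulus locations")
    p <- sample(avail, 1)
    picked <- c(picked, p)
    avail <- avail[abs(avail - p) >= spacing]
  }
  I <- integer(K)
  I[picked] <- 1L
  onsets <- data.frame(onset_s = (sort(picked) - 1) / rate,
                       label = rep(condition_labels()[1:3], length.out = n_stimuli))
  stimulus_train(I, onsets = onsets, rate = rate)
}

#' Generate a complete synthetic dataset
#'
#' Bundles state, stimulus train, skin-conductance channels and heartbeats
#' with the exact generative structure of the model, for parameter-recovery
#' studies. Defaults reproduce the package's simulation-study regime: 500 s at
#' 4 Hz, 25 stimulus impulses, baseline SCR probability 0.01.
#'
#' @param K Number of 4 Hz samples (default 2000).
#' @param params An \code{arousal_params} object (default [default_params()]).
#' @param n_stimuli Number of stimulus impulses (default 25).
#' @param seed Integer seed (required for reproducibility; default 1).
#' @return A list of class \code{arousal_sim} with \code{obs}
#'   (an [observation_set()]), \code{heartbeats}, \code{stimuli}, \code{x}
#'   (true state) and \code{params} (ground truth).
#' @examples
#' d <- make_dataset(K = 400, seed = 2)
#' d$obs
#' @export
make_dataset <- function(K = 2000, params = default_params(), n_stimuli = 25,
                         seed = 1) {
  set.seed(seed)
  stim <- place_stimuli(K, n_stimuli = n_stimuli)
  x <- simulate_state(K, params, I = stim$I)
  sc <- simulate_sc(x, params)
  hb <- simulate_heartbeats(x, params)
  structure(list(obs = observation_set(sc$m, sc$r, sc$s),
                 heartbeats = hb, stimuli = stim, x = x, params = params,
                 seed = seed),
            class = "arousal_sim")
}

#' @export
print.arousal_sim <- function(x, ...) {
  cat("Synthetic arousal dataset (seed", x$seed, ")\n")
  print(x$obs)
  print(x$heartbeats)
  cat("  stimuli:", sum(x$stimuli$I), "impulses\n")
  invisible(x)
}
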