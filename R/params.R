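#' Parameters of the history-dependent inverse Gaussian (HDIG) heartbeat model
#'
#' The HDIG model describes each RR interval as inverse-Gaussian distributed
#' with a mean that depends linearly on the previous \code{q} RR intervals and
#' on the current arousal state, and a fixed shape parameter.
#'
#' @param theta Numeric vector \code{c(theta0, theta1, ..., thetaq, shape)} of
#'   length \code{q + 2}: intercept (s), \code{q} history weights
#'   (dimensionless), and the inverse-Gaussian shape (s).
#' @param eta Coupling from arousal to the RR-interval mean (s per unit
#'   arousal); negative values shorten intervals (speed the heart) as arousal
#'   rises.
#' @return An object of class \code{hdig_params} with elements \code{theta}
#'   (intercept + history weights), \code{shape}, \code{q} and \code{eta}.
#' @examples
#' hdig_params(c(0.27432, 0.83697, -0.10511, 234.22144), eta = -0.005)
#' @export
hdig_params <- function(theta, eta = 0) {
  theta <- as.numeric(theta)
  if (length(theta) < 2L) stop("'theta' needs at least an intercept and a shape")
  q <- length(theta) - 2L
  shape <- theta[length(theta)]
  if (!is.finite(shape) || shape <= 0) stop("HDIG shape (last element of 'theta') must be > 0")
  structure(
    list(theta = theta[seq_len(q + 1L)], shape = shape, q = q, eta = as.numeric(eta)),
    class = "hdig_params"
  )
}

#' @export
print.hdig_params <- function(x, ...) {
  cat("HDIG heartbeat-interval model (order q =", x$q, ")\n")
  cat("  theta:", format(x$theta, digits = 6), "\n")
  cat("  shape:", format(x$shape, digits = 6), "  eta:", format(x$eta, digits = 6), "\n")
  invisible(x)
}

#' Full parameter set of the mixed-observation arousal model
#'
#' Collects every estimable coefficient of the state-space model: the AR(1)
#' latent state, the Bernoulli SCR-event channel (logit link), the two
#' linear-Gaussian skin-conductance channels, and the HDIG heartbeat model.
#'
#' @param rho AR(1) coefficient of the latent arousal state.
#' @param alpha Stimulus input gain (arousal units per stimulus impulse).
#' @param beta0,beta1 Logit-link intercept and slope for SCR-event probability.
#' @param gamma0,gamma1 Intercept and slope of the phasic-derived channel
#'   (log-microsiemens).
#' @param var_v Noise variance of the phasic-derived channel.
#' @param delta0,delta1 Intercept and slope of the tonic channel (microsiemens).
#' @param var_w Noise variance of the tonic channel.
#' @param var_eps Process-noise variance of the latent state.
#' @param hdig An object created by [hdig_params()].
#' @return An object of class \code{arousal_params} (a validated list).
#' @seealso [default_params()] for the parameter set used in the package's
#'   simulation study.
#' @export
model_params <- function(rho, alpha, beta0, beta1 = 1,
                         gamma0, gamma1, var_v,
                         delta0, delta1, var_w,
                         var_eps, hdig) {
  p <- list(rho = rho, alpha = alpha, beta0 = beta0, beta1 = beta1,
            gamma0 = gamma0, gamma1 = gamma1, var_v = var_v,
            delta0 = delta0, delta1 = delta1, var_w = var_w,
            var_eps = var_eps, hdig = hdig)
  validate_params(p)
  structure(p, class = "arousal_params")
}

validate_params <- function(p) {
  num <- c("rho", "alpha", "beta0", "beta1", "gamma0", "gamma1", "var_v",
           "delta0", "delta1", "var_w", "var_eps")
  for (nm in num) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a finite scalar")
  }
  for (nm in c("var_v", "var_w", "var_eps")) {
    if (p[[nm]] <= 0) stop("variance '", nm, "' must be > 0")
  }
  if (abs(p$rho) > 1) warning("|rho| > 1: latent state is nonstationary")
  if (!inherits(p$hdig, "hdig_params")) stop("'hdig' must be an hdig_params object")
  invisible(p)
}

#' @export
print.arousal_params <- function(x, ...) {
  cat("Mixed-observation arousal model parameters\n")
  cat(sprintf("  state : rho = %.5g, alpha = %.5g, var_eps = %.5g\n",
              x$rho, x$alpha, x$var_eps))
  cat(sprintf("  events: beta0 = %.5g, beta1 = %.5g\n", x$beta0, x$beta1))
  cat(sprintf("  phasic: gamma0 = %.5g, gamma1 = %.5g, var_v = %.5g\n",
              x$gamma0, x$gamma1, x$var_v))
  cat(sprintf("  tonic : delta0 = %.5g, delta1 = %.5g, var_w = %.5g\n",
              x$delta0, x$delta1, x$var_w))
  print(x$hdig)
  invisible(x)
}

#' Default simulation-study parameter set
#'
#' The parameter values used throughout the package's simulation study and
#' parameter-recovery tests: a slowly decaying AR(1) arousal state driven by
#' sparse stimulus impulses, a rare-event SCR channel (baseline event
#' probability 0.01), weakly arousal-coupled tonic and phasic-derived channels,
#' and an order-2 HDIG heartbeat model with a small negative arousal coupling.
#'
#' @return An \code{arousal_params} object.
#' @examples
#' default_params()
#' @export
default_params <- function() {
  model_params(
    rho = 0.995, alpha = 0.04,
    beta0 = log(0.01 / 0.99), beta1 = 1,
    gamma0 = 0.35, gamma1 = 0.4, var_v = 0.002,
    delta0 = -0.7, delta1 = 0.2, var_w = 0.003,
    var_eps = 0.03,
    hdig = hdig_params(c(0.27432, 0.83697, -0.10511, 234.22144), eta = -0.005)
  )
}

#' Aligned per-sample observations for the mixed filter
#'
#' @param m Binary vector: SCR event present at each 4 Hz sample.
#' @param r Numeric vector: phasic-derived observation (log-microsiemens).
#' @param s Numeric vector: tonic observation (microsiemens).
#' @param rate Sampling rate in Hz (default 4).
#' @return An object of class \code{observation_set}.
#' @export
observation_set <- function(m, r, s, rate = 4) {
  m <- as.integer(m)
  if (!all(m %in% c(0L, 1L))) stop("'m' must be binary")
  K <- length(m)
  if (length(r) != K || length(s) != K)
    stop("'m', 'r' and 's' must have equal length")
  if (!all(is.finite(r)) || !all(is.finite(s)))
    stop("'r' and 's' must be finite")
  structure(list(m = m, r = as.numeric(r), s = as.numeric(s), rate = rate,
                 K = K),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation_set: K = %d samples at %g Hz (%.1f s), %d SCR events\n",
              x$K, x$rate, x$K / x$rate, sum(x$m)))
  invisible(x)
}

#' Stimulus train: per-sample indicator plus labeled onsets
#'
#' @param I Binary vector of length K: 1 where a stimulus impulse drives the
#'   latent state.
#' @param onsets Optional data.frame with columns \code{onset_s} and
#'   \code{label}; labels must be among \code{CS-}, \code{CS+US-},
#'   \code{CS+US+}, \code{US}.
#' @param rate Sampling rate in Hz.
#' @return An object of class \code{stimulus_train}.
#' @export
stimulus_train <- function(I, onsets = NULL, rate = 4) {
  I <- as.integer(I)
  if (!all(I %in% c(0L, 1L))) stop("'I' must be binary")
  if (!is.null(onsets)) {
    stopifnot(is.data.frame(onsets), all(c("onset_s", "label") %in% names(onsets)))
    bad <- setdiff(unique(onsets$label), condition_labels())
    if (length(bad))
      stop("unknown stimulus label(s) ", paste(bad, collapse = ", "),
           "; allowed: ", paste(condition_labels(), collapse = ", "))
    tmax <- length(I) / rate
    if (any(onsets$onset_s < 0 | onsets$onset_s >= tmax))
      stop("onset times must lie in [0, ", tmax, ")")
  }
  structure(list(I = I, onsets = onsets, rate = rate), class = "stimulus_train")
}

condition_labels <- function() c("CS-", "CS+US-", "CS+US+", "US")
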