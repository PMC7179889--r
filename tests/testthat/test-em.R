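fake_stats <- function(x, v = numeric(length(x)), A = NULL) {
  # sufficient statistics from an exactly known state sequence
  K <- length(x)
  if (is.null(A)) A <- rep(0, K)
  list(U = x^2 + v, U12 = x[-K] * x[-1] + A[-K] * v[-1], x = x, v = v, K = K)
}

test_that("state M-step solves the normal equations exactly on noiseless states", {
  set.seed(40)
  K <- 400
  I <- integer(K); I[seq(25, K, by = 25)] <- 1L
  x <- numeric(K)
  for (k in 2:K) x[k] <- 0.9 * x[k - 1] + 0.5 * I[k] + rnorm(1, 0, 0.1)
  # zero posterior variance injected: recovery is exact least squares
  st <- fake_stats(x)
  up <- mstep_state(st, I)
  ls <- lm(x[-1] ~ 0 + x[-K] + I[-1])
  expect_equal(up$rho, unname(coef(ls)[1]), tolerance = 1e-8)
  expect_equal(up$alpha, unname(coef(ls)[2]), tolerance = 1e-8)

  # exact noiseless AR: recovered to near machine precision
  x2 <- numeric(K)
  for (k in 2:K) x2[k] <- 0.9 * x2[k - 1] + 0.5 * I[k]
  x2 <- x2 + c(0, rnorm(K - 1, 0, 1e-12))  # break exact singularity
  up2 <- mstep_state(fake_stats(x2), I)
  expect_equal(up2$rho, 0.9, tolerance = 1e-6)
  expect_equal(up2$alpha, 0.5, tolerance = 1e-6)

  # no stimuli: alpha dropped, rho from the scalar equation
  up3 <- mstep_state(fake_stats(x), integer(K))
  expect_identical(up3$alpha, 0)
  expect_equal(up3$rho, sum(x[-1] * x[-K]) / sum(x[-K]^2), tolerance = 1e-10)

  # constraint: negative alpha clamped, rho re-solved
  xneg <- numeric(K)
  for (k in 2:K) xneg[k] <- 0.9 * xneg[k - 1] - 0.5 * I[k] + rnorm(1, 0, 0.05)
  upc <- mstep_state(fake_stats(xneg), I, enforce_alpha_nonneg = TRUE)
  expect_identical(upc$alpha, 0)
})

test_that("linear-channel M-step is an exact stationary point", {
  set.seed(41)
  x <- rnorm(300)
  y <- 2 + 3 * x
  up <- mstep_linear_channel(fake_stats(x), y)
  expect_equal(up$intercept, 2, tolerance = 1e-10)
  expect_equal(up$slope, 3, tolerance = 1e-10)
  expect_equal(up$var, 0, tolerance = 1e-10)

  # with posterior variance: gradient of the quadratic objective vanishes
  v <- runif(300, 0.01, 0.1)
  st <- fake_stats(x, v)
  yn <- 1 - 2 * x + rnorm(300, 0, 0.5)
  upv <- mstep_linear_channel(st, yn)
  # objective: E sum (y - a - b x)^2 = sum (y - a - b x_s)^2 + b^2 v
  grad_a <- -2 * sum(yn - upv$intercept - upv$slope * x)
  grad_b <- -2 * sum((yn - upv$intercept - upv$slope * x) * x) +
    2 * upv$slope * sum(v)
  expect_lt(abs(grad_a), 1e-8)
  expect_lt(abs(grad_b), 1e-8)

  expect_error(mstep_linear_channel(fake_stats(rep(1, 10)), rnorm(10)), "singular")
})

test_that("empirical beta strategy reproduces the logit of the event rate", {
  expect_equal(beta_empirical(integer(10), p0 = 0.01)$beta0, -4.5951,
               tolerance = 1e-4)
  expect_identical(beta_empirical(integer(10), p0 = 0.5)$beta0, 0)
  m <- integer(300); m[c(3, 150, 299)] <- 1L
  expect_equal(beta_empirical(m)$beta0, log(0.01 / 0.99), tolerance = 1e-12)
  expect_equal(beta_empirical(m)$beta1, 1)
  expect_error(beta_empirical(integer(50)), "strictly")
  expect_error(beta_empirical(rep(1L, 50)), "strictly")
})

test_that("Taylor beta M-step collapses to logistic regression at zero variance", {
  set.seed(42)
  K <- 5000
  x <- rnorm(K, 0, 1.5)
  p <- plogis(-2 + 0.8 * x)
  m <- rbinom(K, 1, p)
  bt <- beta_taylor(m, x, numeric(K), start = c(-1, 1))
  glm_fit <- glm(m ~ x, family = binomial())
  expect_equal(bt$beta0, unname(coef(glm_fit)[1]), tolerance = 1e-6)
  expect_equal(bt$beta1, unname(coef(glm_fit)[2]), tolerance = 1e-6)

  # recovery near truth at this sample size
  set.seed(43)
  x2 <- rnorm(K, 0, 2)
  m2 <- rbinom(K, 1, plogis(-4.6 + x2))
  bt2 <- beta_taylor(m2, x2, numeric(K), start = c(-4, 1))
  expect_lt(abs(bt2$beta0 + 4.6), 0.3)
  expect_lt(abs(bt2$beta1 - 1), 0.2)

  expect_error(beta_taylor(integer(100), rnorm(100), numeric(100)), "degenerate")
})

test_that("approximate expected point-process likelihood behaves as derived", {
  d <- shared_sim()
  p <- d$params
  traj <- sa_smooth(forward_filter(d$obs, d$heartbeats, d$stimuli, p))

  # zero smoothed variance -> plug-in log likelihood of the binary bins
  traj0 <- traj
  traj0$var_smooth <- numeric(nrow(traj))
  q2_plug <- q2bar(traj0, d$heartbeats, p)
  pp <- arousaltrack:::pp_precompute(d$heartbeats, p$hdig, K = nrow(traj))
  ok <- pp$valid
  kk <- row(pp$w)[ok]
  mu <- pmax(pp$mu_hat[ok] + p$hdig$eta * traj$x_smooth[kk], 1e-6)
  lam <- pmax(arousaltrack:::cif_derivs(pp$w[ok], mu, p$hdig$shape)$lambda, 1e-300)
  manual <- sum(pp$n[ok] * log(pmin(lam * pp$delta, 1 - 1e-12)) - lam * pp$delta)
  expect_equal(q2_plug, manual, tolerance = 1e-8)

  # eta = 0: invariant to shifts of the state trajectory
  p0 <- p
  p0$hdig <- hdig_params(c(p$hdig$theta, p$hdig$shape), eta = 0)
  trajA <- traj; trajB <- traj
  trajB$x_smooth <- trajB$x_smooth + 5
  expect_equal(q2bar(trajA, d$heartbeats, p0), q2bar(trajB, d$heartbeats, p0),
               tolerance = 1e-10)
})

test_that("variance correction in the expected likelihood matches Monte Carlo", {
  d <- shared_sim()
  p <- d$params
  hdig <- p$hdig
  pp <- arousaltrack:::pp_precompute(d$heartbeats, hdig, K = 100)
  traj <- sa_smooth(forward_filter(
    observation_set(d$obs$m[1:100], d$obs$r[1:100], d$obs$s[1:100]),
    d$heartbeats, stimulus_train(d$stimuli$I[1:100]), p))
  q2_approx <- arousaltrack:::q2bar_pp(traj, pp, hdig)

  set.seed(44)
  draws <- 4000
  mc <- replicate(draws, {
    xs <- rnorm(100, traj$x_smooth, sqrt(traj$var_smooth))
    ok <- pp$valid
    kk <- row(pp$w)[ok]
    mu <- pmax(pp$mu_hat[ok] + hdig$eta * xs[kk], 1e-6)
    lam <- pmax(arousaltrack:::cif_derivs(pp$w[ok], mu, hdig$shape)$lambda, 1e-300)
    sum(pp$n[ok] * log(lam * pp$delta) - lam * pp$delta)
  })
  se <- sd(mc) / sqrt(draws)
  expect_lt(abs(q2_approx - mean(mc)), 3 * se + 0.02 * abs(mean(mc) - q2_approx) + 0.5)
})

test_that("EM reduces to linear-Gaussian EM when only Gaussian channels inform", {
  p <- gaussian_only_params()
  set.seed(45)
  K <- 300
  I <- integer(K); I[seq(30, K, 40)] <- 1L
  x <- simulate_state(K, p, I = I)
  sc <- simulate_sc(x, p)
  obs <- observation_set(integer(K), sc$r, sc$s)
  stim <- stimulus_train(I)
  hd0 <- hdig_params(c(0.9, 0, 200), eta = 0)
  cfg <- em_config(max_iter = 5, tolerance = 1e-15)
  # start from the package's default initialization, with the binary channel
  # switched off (beta1 = 0; the event series is empty here)
  init <- suppressWarnings(model_params(
    rho = 0.99, alpha = 0.01, beta0 = -4, beta1 = 0,
    gamma0 = mean(sc$r), gamma1 = 1, var_v = var(sc$r),
    delta0 = mean(sc$s), delta1 = 1, var_w = var(sc$s),
    var_eps = 0.01, hdig = hd0))
  fit <- run_em(obs, NULL, stim, hd0, cfg, init = init)

  # oracle EM: same E-step via the textbook Kalman/RTS, same closed-form
  # M-steps, same initialization, same iteration count
  pars <- list(rho = 0.99, alpha = 0.01,
               g0 = mean(sc$r), g1 = 1, vv = var(sc$r),
               d0 = mean(sc$s), d1 = 1, vw = var(sc$s), q = 0.01)
  for (it in 1:5) {
    o <- kalman_oracle(sc$r, sc$s, I, pars$rho, pars$alpha, pars$q,
                       pars$g0, pars$g1, pars$vv, pars$d0, pars$d1, pars$vw)
    st <- list(U = o$x_smooth^2 + o$var_smooth,
               U12 = o$x_smooth[-K] * o$x_smooth[-1] + o$A[-K] * o$var_smooth[-1],
               x = o$x_smooth, v = o$var_smooth, K = K)
    us <- mstep_state(st, I)
    ur <- mstep_linear_channel(st, sc$r)
    usb <- mstep_linear_channel(st, sc$s)
    pars <- list(rho = us$rho, alpha = us$alpha, q = us$var_eps,
                 g0 = ur$intercept, g1 = ur$slope, vv = ur$var,
                 d0 = usb$intercept, d1 = usb$slope, vw = usb$var)
  }
  expect_equal(fit$params$rho, pars$rho, tolerance = 1e-6)
  expect_equal(fit$params$gamma1, pars$g1, tolerance = 1e-6)
  expect_equal(fit$params$var_v, pars$vv, tolerance = 1e-6)
  expect_equal(fit$params$var_eps, pars$q, tolerance = 1e-6)
})

test_that("EM control paths: immediate convergence, gate stop, iteration cap", {
  d <- shared_sim()
  obs <- observation_set(d$obs$m[1:300], d$obs$r[1:300], d$obs$s[1:300])
  stim <- stimulus_train(d$stimuli$I[1:300])
  hd <- d$params$hdig

  fit1 <- run_em(obs, NULL, stim, hd, em_config(tolerance = Inf, max_iter = 50))
  expect_identical(fit1$iterations, 1L)
  expect_identical(fit1$stop_reason, "converged")

  fit2 <- run_em(obs, NULL, stim, hd, em_config(max_iter = 3, tolerance = 1e-12))
  expect_identical(fit2$stop_reason, "max_iter")
  expect_identical(fit2$iterations, 3L)

  # standardized channels have unit variance, so the first-iteration variance
  # updates sit well inside the 0.1 gate: immediate overfit stop, parameters
  # left at initialization
  fit3 <- run_em(obs, NULL, stim, hd,
                 em_config(use_gate = TRUE, overfit_gate = 1e6,
                           standardize_continuous = TRUE))
  expect_identical(fit3$stop_reason, "overfit_stop")
  expect_identical(fit3$iterations, 1L)
  expect_equal(fit3$params$rho, 0.99)  # untouched initialization
})

test_that("expected complete-data likelihood trends upward across EM iterations", {
  d <- shared_sim()
  obs <- observation_set(d$obs$m[1:800], d$obs$r[1:800], d$obs$s[1:800])
  stim <- stimulus_train(d$stimuli$I[1:800])
  bt <- d$heartbeats$beat_times
  hb <- heartbeat_series(bt[bt <= 200], T = 200)
  fit <- run_em(obs, hb, stim, d$params$hdig, em_config(max_iter = 15))
  # full EM surrogate: state + Gaussian channels + Bernoulli + point process
  # (the Gaussian posterior approximation voids a strict guarantee)
  tot <- fit$q1bar + fit$q2bar + fit$q_gauss
  expect_gte(mean(diff(tot) >= -1e-6), 0.9)
})

test_that("eta grid selection honours the KS constraint and tie rules", {
  # single-value grid returns trivially
  d <- shared_sim()
  obs <- observation_set(d$obs$m[1:600], d$obs$r[1:600], d$obs$s[1:600])
  stim <- stimulus_train(d$stimuli$I[1:600])
  bt <- d$heartbeats$beat_times
  hb <- heartbeat_series(bt[bt <= 150], T = 150)
  hd <- fit_hdig_ml(hb$rr, 2)
  cfg <- em_config(max_iter = 8, eta_grid = -1e-3)
  sel <- select_eta(obs, hb, stim, hd, cfg)
  expect_identical(sel$eta_best, -1e-3)
  expect_identical(nrow(sel$report), 1L)

  # tie rule: flat q2bar -> smallest |eta| among admissible candidates
  grid <- c(-1e-4, -1e-3)
  q2v <- c(-100, -100 + 1e-8)
  adm <- c(TRUE, TRUE)
  cand <- which(adm)
  near <- cand[q2v[cand] >= max(q2v[cand]) - 1e-6]
  expect_identical(grid[near[which.min(abs(grid[near]))]], -1e-4)
})
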