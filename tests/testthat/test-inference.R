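test_that("maximum likelihood recovers identifiable truth and closed forms", {
  spec <- fig1_spec()
  th0 <- log(c(2, 0.4))
  x <- predict(spec, th0)    # noise-free observation
  th_hat <- mle(spec, x, seed = 1)
  expect_lt(sqrt(sum((predict(spec, as.numeric(th_hat)) - x)^2)), 1e-6)
  # one-parameter linear model: theta_hat = x
  sl <- linear_model(noise_sigma = 0.5, domain = c(-3, 3))
  expect_equal(as.numeric(mle(sl, 0.77, seed = 2)), 0.77, tolerance = 1e-6)
  # dense-grid oracle on a noisy observation
  xr <- simulate_observation(spec, th0, seed = 3)
  th_hat2 <- as.numeric(mle(spec, xr, seed = 4))
  gr <- seq(-6, 6, length.out = 400)
  best <- -Inf
  for (t1 in gr) for (t2 in gr[gr <= t1]) {
    v <- loglikelihood(spec, xr, c(t1, t2))
    if (v > best) best <- v
  }
  expect_gte(loglikelihood(spec, xr, th_hat2), best - 1e-4)
  expect_error(mle(spec, c(NA, 1)), "finite")
})

test_that("discrete posteriors follow exact Bayes arithmetic", {
  spec <- fig1_spec()
  locs <- rbind(log(c(2, 0.5)), log(c(1, 0.2)), log(c(0.5, 0.1)))
  pr <- atomic_prior(locs, c(0.2, 0.3, 0.5))
  x <- simulate_observation(spec, locs[2, ], seed = 5)
  pw <- posterior_weights(pr, spec, x)
  direct <- c(0.2, 0.3, 0.5) * sapply(1:3, function(a)
    exp(loglikelihood(spec, x, locs[a, ])))
  expect_equal(pw, direct / sum(direct), tolerance = 1e-12)
  # equal likelihoods leave a uniform prior uniform
  s2 <- decay_model(c(0.5, 0.5), times = c(1, 3))
  pr_u <- atomic_prior(rbind(c(0.3, 0.1), c(0.3, 0.1), c(0.3, 0.1)))
  expect_equal(posterior_weights(pr_u, s2, c(0.5, 0.3)), rep(1 / 3, 3))
  # dominance: x at one atom, others far away
  sl <- linear_model(noise_sigma = 0.1, domain = c(0, 100))
  prd <- atomic_prior(matrix(c(10, 50, 90), 3))
  expect_equal(posterior_weights(prd, sl, 10)[1], 1, tolerance = 1e-12)
})

test_that("posterior sampling matches conjugate and quadrature oracles", {
  # flat prior, linear-Gaussian model: posterior is N(x, sigma^2)
  sl <- linear_model(noise_sigma = 0.4, domain = c(-10, 10))
  ps <- posterior_sample(sl, x = 1.3, prior = "flat", n = 8000, seed = 6)
  expect_lt(ps$diagnostics$rhat, 1.1)
  th <- ps$draws[, 1]
  expect_equal(mean(th), 1.3, tolerance = 4 * 0.4 / sqrt(200))
  expect_equal(stats::sd(th), 0.4, tolerance = 0.05)
  # truncated domain: quadrature posterior mean
  st <- linear_model(noise_sigma = 0.5, domain = c(0, 1))
  xo <- -0.3
  Zq <- stats::integrate(function(t) dnorm(xo, t, 0.5), 0, 1)$value
  mq <- stats::integrate(function(t) t * dnorm(xo, t, 0.5), 0, 1)$value / Zq
  pst <- posterior_sample(st, xo, "flat", n = 8000, seed = 7)
  expect_lt(abs(mean(pst$draws[, 1]) - mq), 0.03)
  # sigma -> 0 concentrates the posterior at the MLE
  s0 <- linear_model(noise_sigma = 0.01, domain = c(-10, 10))
  ps0 <- posterior_sample(s0, 0.5, "flat", n = 4000, seed = 8)
  expect_lt(stats::sd(ps0$draws[, 1]), 0.02)
})

test_that("posterior deviation matches its enumeration and quadrature forms", {
  spec <- fig1_spec()
  # single-atom prior: Delta is the distance to that atom's prediction
  th1 <- log(c(1, 0.4))
  pr <- atomic_prior(matrix(th1, 1))
  x <- predict(spec, th1) + c(0.05, -0.02)
  rep1 <- posterior_deviation(spec, pr, x, seed = 9)
  y1 <- predict(spec, th1)
  yh <- predict(spec, rep1$theta_hat)
  expect_equal(rep1$delta, sqrt(sum((yh - y1)^2)) / 0.1, tolerance = 1e-9)
  expect_gte(rep1$delta, 0)
  # x exactly on the atom's prediction: Delta -> 0
  rep0 <- posterior_deviation(spec, pr, predict(spec, th1), seed = 10)
  expect_lt(rep0$delta, 1e-6)
  # 1-d truncated flat prior vs quadrature
  st <- linear_model(noise_sigma = 0.5, domain = c(0, 1))
  xo <- -0.3
  Zq <- stats::integrate(function(t) dnorm(xo, t, 0.5), 0, 1)$value
  mq <- stats::integrate(function(t) t * dnorm(xo, t, 0.5), 0, 1)$value / Zq
  delta_q <- abs(0 - mq) / 0.5    # theta_hat clamps to the boundary 0
  rept <- posterior_deviation(st, "flat", xo, n = 8000, seed = 11)
  expect_equal(rept$delta, delta_q, tolerance = 0.05)
})

test_that("bias pressure at the MLE tracks the posterior deviation across observations", {
  spec <- fig1_spec()
  js <- sample_jeffreys(spec, n = 2e4, seed = 41)
  popt <- optimize_prior(spec, K_init = 30, tol_bits = 0.15, max_iter = 40,
                         n_x = 600, seed = 42)
  mi <- mutual_information(js, spec, n_x = 400, seed = 43, n_outer = 200,
                           n_theta = 4000)
  set.seed(44)
  deltas <- bvals <- numeric(30)
  for (i in 1:30) {
    a <- sample.int(nrow(popt$locations), 1, prob = popt$weights)
    x <- simulate_observation(spec, popt$locations[a, ],
                              seed = 500 + i)
    pd <- suppressWarnings(posterior_deviation(spec, js, x, n = 2000,
                                               seed = 600 + i))
    b <- bias_pressure(pd$theta_hat, js, spec, n_x = 400,
                       seed = 700 + i, mi = mi, method = "plugin",
                       n_theta = 4000)
    deltas[i] <- pd$delta
    bvals[i] <- b$point
  }
  expect_gt(stats::cor(deltas, bvals, method = "spearman"), 0.5)
})

test_that("the information-noise curve yields a sane effective dimension", {
  # one long parameter: slope must approach 1
  sl <- linear_model(noise_sigma = 1, domain = c(0, 4))
  curve <- effective_dimension(sl, sigmas = c(1, 0.5, 0.25, 0.125),
                               seed = 3, K_init = 10, tol_bits = 0.05,
                               max_iter = 40, n_x = 500)
  expect_true(all(diff(curve$I_bits) > -1e-9))
  expect_equal(curve$d_eff, 1, tolerance = 0.2)
  expect_error(effective_dimension(sl, sigmas = c(1, 2, 3)), "decreasing")
  # four-rate model: information rises as noise falls, the effective
  # dimension stays within [~1, d], and the local slope steepens as the
  # window moves to smaller noise
  f2 <- build_preset("fig2")
  curve2 <- effective_dimension(f2, sigmas = c(0.8, 0.4, 0.2, 0.1), seed = 4,
                                K_init = 25, tol_bits = 0.15, max_iter = 40,
                                n_x = 600)
  expect_true(all(diff(curve2$I_bits) > -1e-9))
  expect_gt(curve2$d_eff, 0.8)
  expect_lt(curve2$d_eff, 4 + 2 * max(curve2$slope_stderr, 0.3))
  slope_large_sigma <- diff(curve2$I_nats[1:2]) / log(2)
  expect_gt(curve2$d_eff, slope_large_sigma)
})
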