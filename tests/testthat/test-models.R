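test_that("decay predictions match the closed form", {
  spec <- decay_model(c(0.8, 0.2), times = c(1, 3))
  # equal amplitude fractions sum to y0 = 1 at t = 0
  spec0 <- decay_model(rep(1 / 3, 3), times = c(0, 1, 2), ordered = FALSE)
  expect_equal(predict(spec0, c(0.3, -0.1, 0.2))[1], 1)
  # equal rates collapse the amplitudes
  expect_equal(predict(decay_model(c(0.8, 0.2), times = 3),
                       log(c(1, 1))),
               exp(-3))
  # frozen high-precision value
  expect_equal(predict(spec, log(c(2, 1)))[1],
               0.8 * exp(-2) + 0.2 * exp(-1), tolerance = 1e-12)
  expect_equal(predict(spec, log(c(2, 1)))[1], 0.18184411, tolerance = 1e-7)
  # monotone decreasing in t for positive rates and amplitudes
  spec_m <- decay_model(c(0.5, 0.3, 0.2), times = seq(0.2, 6, by = 0.2),
                        ordered = FALSE)
  y <- predict(spec_m, c(0.7, -0.3, 1.1))
  expect_true(all(diff(y) < 0))
  expect_error(predict(spec, c(1, NaN)), "finite")
  expect_error(predict(spec, 1), "length")
})

test_that("Gaussian log-likelihood matches closed forms and dnorm oracle", {
  spec <- decay_model(c(0.8, 0.2), times = c(1, 3))
  th <- log(c(2, 1))
  y <- predict(spec, th)
  # zero residual
  expect_equal(loglikelihood(spec, y, th), -(2 / 2) * log(2 * pi * 0.01))
  # one-sigma residual in m = 1
  s1 <- one_rate_spec()
  th1 <- 0.2
  x1 <- predict(s1, th1) + 0.1
  expect_equal(loglikelihood(s1, x1, th1), -0.5 - 0.5 * log(2 * pi * 0.01))
  # independent density oracle: sum of univariate normal log-densities
  set.seed(4)
  for (i in 1:5) {
    thr <- sort(runif(2, -2, 2), decreasing = TRUE)
    xr <- rnorm(2)
    expect_equal(loglikelihood(spec, xr, thr),
                 sum(dnorm(xr, predict(spec, thr), 0.1, log = TRUE)),
                 tolerance = 1e-10)
  }
  expect_error(loglikelihood(spec, c(1, 2, 3), th), "obs_dim")
  # maximized over x at x = y(theta)
  expect_true(loglikelihood(spec, y, th) >
                loglikelihood(spec, y + 0.01, th))
})

test_that("simulation is reproducible, unbiased, and respects the sigma -> 0 limit", {
  spec <- fig1_spec()
  th <- log(c(1.5, 0.5))
  x1 <- simulate_observation(spec, th, seed = 9)
  x2 <- simulate_observation(spec, th, seed = 9)
  expect_identical(x1, x2)
  spec0 <- spec
  spec0$noise_sigma <- 1e-12
  expect_equal(simulate_observation(spec0, th, seed = 1), predict(spec, th),
               tolerance = 1e-9)
  # CLT: mean of many draws within 3 standard errors
  X <- simulate_observation(spec, th, seed = 2, n = 1e4)
  se <- 0.1 / sqrt(1e4)
  expect_true(all(abs(colMeans(X) - predict(spec, th)) < 3.5 * se))
  expect_error(simulate_observation(spec, c(10, 0), seed = 1), "domain")
})

test_that("replication scales the information and nothing else", {
  spec <- fig1_spec()
  th <- log(c(1, 0.3))
  expect_error(replicate_spec(spec, 0), ">= 1")
  expect_identical(replicate_spec(spec, 1L), spec)
  r4 <- replicate_spec(spec, 4L)
  expect_equal(spec_sigma(r4), spec_sigma(spec) / 2)
  expect_equal(fisher_metric(r4, th)$matrix, 4 * fisher_metric(spec, th)$matrix)
})

test_that("enzyme models conserve enzyme, start product at zero, and obey QSSA limits", {
  mm3 <- build_preset("mm3")
  th <- log(c(3, 0.5, 0.8))
  traj <- infoprior:::enzyme_solve(mm3, th, full = TRUE)
  expect_true(all(traj >= -1e-9))
  # [E] + [ES] conserved
  expect_equal(unname(traj[, "E"] + traj[, "ES"]), rep(1, nrow(traj)),
               tolerance = 1e-7)
  mm3b <- enzyme_model("mm3", times = c(1e-8, 1, 2))
  expect_lt(predict(mm3b, th)[1], 1e-6)

  pp <- build_preset("pingpong8")
  thp <- log(c(2, 1, 0.5, 1.5, 2, 1, 0.3, 0.7))
  tr <- infoprior:::enzyme_solve(pp, thp, full = TRUE)
  tot <- rowSums(tr[, c("E", "EA", "EsP", "Es", "EsB", "EQ")])
  expect_equal(unname(tot), rep(1, nrow(tr)), tolerance = 1e-7)
  expect_true(all(tr >= -1e-9))

  # Michaelis-Menten quasi-steady-state: fast complex kinetics, scarce enzyme
  kf <- exp(5); kr <- exp(3); kp <- 0.5; E0 <- 0.005
  spec_q <- enzyme_model("mm3", times = 1:5,
                         init = c(E = E0, S = 1, ES = 0, P = 0))
  P_full <- predict(spec_q, log(c(kf, kr, kp)))
  Km <- (kr + kp) / kf
  red <- deSolve::lsoda(c(S = 1), times = 0:5, func = function(t, y, p) {
    list(-kp * E0 * y[1] / (Km + y[1]))
  }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  P_qssa <- 1 - red[-1, "S"]
  expect_lt(max(abs(P_full - P_qssa) / P_qssa), 0.01)
})

test_that("domain checks include box bounds and rate ordering", {
  spec <- fig1_spec()
  expect_true(in_domain(spec, c(1, 0)))
  expect_false(in_domain(spec, c(0, 1)))   # violates k1 >= k2
  expect_false(in_domain(spec, c(7, 0)))
  expect_false(in_domain(spec, c(1, NA)))
})
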