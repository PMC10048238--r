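test_that("the atomic marginal is an exact log-sum-exp mixture", {
  spec <- fig1_spec()
  th1 <- log(c(2, 0.5))
  x <- simulate_observation(spec, th1, seed = 1)
  # single atom collapses to the likelihood
  p1 <- atomic_prior(matrix(th1, 1))
  expect_equal(marginal_logdensity(p1, spec, x), loglikelihood(spec, x, th1))
  # two atoms with identical predictions collapse too
  s2 <- decay_model(c(0.5, 0.5), times = c(1, 3))
  pa <- atomic_prior(rbind(c(0.4, 0.1), c(0.4, 0.1)))
  xx <- c(0.3, 0.2)
  expect_equal(marginal_logdensity(pa, s2, xx),
               loglikelihood(s2, xx, c(0.4, 0.1)))
  # direct summation oracle for 5 random atoms
  set.seed(6)
  locs <- t(replicate(5, sort(runif(2, -3, 3), decreasing = TRUE)))
  w <- runif(5); w <- w / sum(w)
  pr <- atomic_prior(locs, w)
  direct <- log(sum(w * sapply(seq_len(5), function(a)
    exp(loglikelihood(spec, x, locs[a, ])))))
  expect_equal(marginal_logdensity(pr, spec, x), direct, tolerance = 1e-12)
  expect_error(marginal_logdensity(list(), spec, x), "prior")
})

test_that("KL to the marginal matches closed forms for atomic priors", {
  spec <- fig1_spec()
  th <- log(c(1.5, 0.7))
  # prior concentrated at theta itself: zero divergence, every draw
  expect_equal(kl_to_marginal(spec, th, atomic_prior(matrix(th, 1)),
                              n_x = 200, seed = 1)$point, 0)
  # single atom elsewhere: Gaussian-Gaussian closed form
  th2 <- log(c(0.5, 0.2))
  est <- kl_to_marginal(spec, th, atomic_prior(matrix(th2, 1)),
                        n_x = 4000, seed = 2)
  expect_equal(est$point, gaussian_kl(spec, th, th2),
               tolerance = 6 * est$stderr / max(est$point, 1))
  # two well-separated equal atoms: log 2 nats at either atom
  sl <- linear_model(noise_sigma = 0.1, domain = c(0, 100))
  pr2 <- atomic_prior(matrix(c(10, 15), 2))   # 50 sigma apart
  est2 <- kl_to_marginal(sl, 10, pr2, n_x = 2000, seed = 3)
  expect_equal(est2$point, log(2), tolerance = 1e-6)
  expect_equal(quad_kl_atomic(sl, 10, pr2), log(2), tolerance = 1e-6)
  expect_error(kl_to_marginal(spec, th, atomic_prior(matrix(th, 1)),
                              n_x = 10), "at least 100")
})

test_that("mutual information obeys the channel bounds", {
  # single atom carries no information
  sl <- linear_model(noise_sigma = 1, domain = c(0, 100))
  expect_equal(mutual_information(atomic_prior(matrix(5, 1)), sl,
                                  n_x = 200, seed = 1)$point, 0)
  # K perfectly distinguishable symbols: log K nats
  pr8 <- spaced_atoms(8, gap = 60)
  mi8 <- mutual_information(pr8, sl, n_x = 2000, seed = 2)
  expect_equal(mi8$point, log(8), tolerance = 1e-4)
  # input entropy bound I <= log K for squeezed atoms
  pr_sq <- spaced_atoms(6, gap = 1.2)
  mi_sq <- mutual_information(pr_sq, sl, n_x = 2000, seed = 3)
  expect_lt(mi_sq$point, log(6))
  expect_gt(mi_sq$point, 0)
  # Gaussian capacity cap: I <= (m/2) log(1 + Var(y)/sigma^2)
  ys <- drop(infoprior:::predict_matrix(sl, pr_sq$locations))
  vy <- sum(pr_sq$weights * ys^2) - sum(pr_sq$weights * ys)^2
  expect_lt(mi_sq$point, 0.5 * log(1 + vy / 1) + 3 * mi_sq$stderr)
})

test_that("bias pressure has zero prior expectation and propagated bounds", {
  spec <- fig1_spec()
  set.seed(9)
  locs <- t(replicate(5, sort(runif(2, -4, 4), decreasing = TRUE)))
  w <- runif(5); w <- w / sum(w)
  pr <- atomic_prior(locs, w)
  # independent random streams for I and each atom's D
  mi <- mutual_information(pr, spec, n_x = 2000, seed = 100)
  bs <- lapply(seq_len(5), function(a)
    bias_pressure(locs[a, ], pr, spec, n_x = 2000, seed = 200 + a, mi = mi))
  bsum <- sum(w * vapply(bs, `[[`, 0, "point"))
  se <- sqrt(sum((w * vapply(bs, `[[`, 0, "stderr"))^2) + mi$stderr^2)
  expect_lt(abs(bsum), 3 * se)
  # bounds bracket the point for each estimate
  for (b in bs) {
    expect_lte(b$lower, b$point + 1e-12)
    expect_lte(b$point, b$upper + 1e-12)
  }
  # single-atom prior at theta: b = 0 exactly
  b0 <- bias_pressure(locs[1, ], atomic_prior(matrix(locs[1, ], 1)), spec,
                      n_x = 200, seed = 5)
  expect_equal(b0$point, 0)
})

test_that("sample-prior KL bounds bracket a quadrature oracle in one dimension", {
  spec <- linear_model(noise_sigma = 0.3, domain = c(-30, 30))
  set.seed(5)
  tau <- 2; mu0 <- 1
  draws <- matrix(rnorm(4000, mu0, tau), ncol = 1)
  ldp <- function(th) {
    if (!in_domain(spec, th)) return(-Inf)
    dnorm(th, mu0, tau, log = TRUE)
  }
  ws <- weighted_sample(draws, source = "custom", logdensity = ldp)
  for (th in c(3, 6)) {
    f <- function(x) dnorm(x, th, 0.3) *
      (dnorm(x, th, 0.3, log = TRUE) -
         dnorm(x, mu0, sqrt(0.09 + tau^2), log = TRUE))
    Dq <- stats::integrate(f, th - 5, th + 5)$value
    est <- kl_to_marginal(spec, th, ws, n_x = 500, seed = 40 + th,
                          method = "bridge", n_x_bridge = 24)
    slack <- 4 * max(est$stderr, 0.05 * Dq)
    expect_lt(est$lower, Dq + slack)
    expect_gt(est$upper, Dq - slack)
    expect_lt(abs(est$point - Dq), slack + 0.3)
  }
})

test_that("plug-in marginals under-estimate log p(x) far from the support", {
  # Jensen direction of the documented plug-in bias
  spec <- linear_model(noise_sigma = 0.3, domain = c(-30, 30))
  set.seed(6)
  ws <- weighted_sample(matrix(rnorm(2000, 0, 1), ncol = 1))
  truth <- dnorm(8, 0, sqrt(1 + 0.09), log = TRUE)
  expect_lt(marginal_logdensity(ws, spec, 8), truth)
})

test_that("mutual information grows with repetition", {
  spec <- fig1_spec()
  set.seed(12)
  locs <- t(replicate(4, sort(runif(2, -3, 3), decreasing = TRUE)))
  pr <- atomic_prior(locs)
  mi1 <- mutual_information(pr, spec, n_x = 3000, seed = 31)
  mi4 <- mutual_information(pr, replicate_spec(spec, 4L), n_x = 3000,
                            seed = 31)
  expect_gt(mi4$point, mi1$point - 3 * sqrt(mi1$stderr^2 + mi4$stderr^2))
})

test_that("worst-case bias of a single-atom prior matches a dense-grid oracle", {
  spec <- fig1_spec()
  th0 <- log(c(1, 0.3))
  pr <- atomic_prior(matrix(th0, 1))
  B <- worst_case_bias(pr, spec, n_x = 2000, seed = 3, n_lhs = 24)
  # brute force on a grid: for a point prior, b(theta) = ||y - y0||^2/(2 s^2)
  gr <- seq(-6, 6, length.out = 180)
  y0 <- predict(spec, th0)
  best <- 0
  for (t1 in gr) {
    y1 <- 0.8 * exp(-exp(t1) * c(1, 3))
    for (t2 in gr[gr <= t1]) {
      y <- y1 + 0.2 * exp(-exp(t2) * c(1, 3))
      v <- sum((y - y0)^2) / (2 * 0.01)
      if (v > best) best <- v
    }
  }
  expect_equal(B$point, best, tolerance = 0.02)
  expect_gte(B$point, 0)
})
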