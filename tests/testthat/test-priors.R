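test_that("Jeffreys log-density is repetition-invariant up to a constant shift", {
  spec <- fig1_spec()
  r9 <- replicate_spec(spec, 9L)
  ths <- list(log(c(1, 0.5)), c(2, -1), c(0.3, 0.3 - 1e-3))
  shifts <- vapply(ths, function(th)
    jeffreys_logdensity(r9, th) - jeffreys_logdensity(spec, th), 0)
  expect_equal(shifts, rep((2 / 2) * log(9), 3), tolerance = 1e-9)
  expect_identical(jeffreys_logdensity(spec, c(10, 0)), -Inf)
  # dead parameter
  sd0 <- decay_model(c(1, 0), times = c(1, 2), ordered = FALSE)
  expect_identical(as.numeric(jeffreys_logdensity(sd0, c(0.5, 0.2))), -Inf)
})

test_that("the Jeffreys sampler is calibrated on a constant-metric model", {
  # y = theta: constant metric, so Jeffreys is uniform on the interval
  spec <- linear_model(noise_sigma = 1, domain = c(-2, 3))
  ws <- sample_jeffreys(spec, n = 8000, seed = 5)
  expect_lt(ws$diagnostics$rhat, 1.1)
  ks <- suppressWarnings(stats::ks.test(ws$draws[seq(1, 8000, by = 8), 1],
                                        "punif", -2, 3))
  expect_gt(ks$p.value, 0.01)
})

test_that("fig1 Jeffreys pushes forward to the uniform density on prediction space", {
  spec <- fig1_spec()
  ws <- sample_jeffreys(spec, n = 4e4, seed = 7)
  # thin hard enough that draws are approximately independent
  Ymc <- infoprior:::predict_matrix(spec, ws$draws[seq(1, 4e4, by = 100), ])
  # independent route to uniform-on-Y: importance-resample uniform theta
  # draws with weight |det J|, the area element of the prediction map
  set.seed(8)
  Th <- infoprior:::domain_random_points(spec, 4e4)
  wts <- apply(Th, 1, function(th) {
    s <- svd(model_jacobian(spec, th), nu = 0, nv = 0)$d
    prod(s)
  })
  Yiw <- infoprior:::predict_matrix(spec, Th)
  pick <- sample.int(nrow(Yiw), 400, prob = wts / sum(wts))
  for (j in 1:2) {
    ks <- suppressWarnings(stats::ks.test(Ymc[, j], Yiw[pick, j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("Jeffreys sampling is invariant in distribution under reparametrization", {
  # route A: sample in theta = log k and push through exp; route B: sample
  # the k-parametrized Jeffreys density directly with the same MCMC engine.
  # The two pushforward marginals of k must agree.
  spec <- decay_model(c(0.8, 0.2), times = c(1, 3), domain = c(-2, 2))
  wsA <- sample_jeffreys(spec, n = 2e4, seed = 21)
  kA <- exp(wsA$draws)

  ld_k <- function(k) {
    if (any(k < exp(-2)) || any(k > exp(2)) || k[1] < k[2]) return(-Inf)
    th <- log(k)
    s <- svd(model_jacobian(spec, th) %*% diag(1 / k), nu = 0, nv = 0)$d
    if (any(s <= 0)) return(-Inf)
    sum(log(s)) - 2 * log(0.1)
  }
  set.seed(22)
  init <- t(replicate(4, sort(exp(runif(2, -2, 2)), decreasing = TRUE)))
  resB <- infoprior:::adaptive_metropolis(ld_k, init, n_keep = 2e4)
  expect_lt(resB$rhat, 1.2)
  for (j in 1:2) {
    qA <- quantile(kA[, j], c(0.25, 0.5, 0.75))
    qB <- quantile(resB$draws[, j], c(0.25, 0.5, 0.75))
    expect_equal(unname(qA), unname(qB), tolerance = 0.08)
  }
})

test_that("log-normal prior density is a normalized symmetric mode at theta_bar", {
  expect_error(lognormal_logdensity(0, sigma_bar = -1), "sigma_bar")
  th <- c(0.4, -0.4)
  expect_equal(lognormal_logdensity(th, 0, 1),
               lognormal_logdensity(-th, 0, 1))
  expect_gt(lognormal_logdensity(c(0, 0)), lognormal_logdensity(c(0.3, 0.1)))
  # integrates to one in d = 1
  expect_equal(stats::integrate(function(t)
    exp(vapply(t, lognormal_logdensity, 0)), -Inf, Inf)$value, 1,
    tolerance = 1e-8)
  ws <- sample_lognormal(fig1_spec(), n = 4000, seed = 2)
  expect_true(all(ws$draws >= -6 & ws$draws <= 6))
  expect_true(all(diff(t(ws$draws)) <= 0))  # ordered cone
})

test_that("prior files round-trip with validation", {
  pr <- atomic_prior(matrix(c(0.1, -0.4, 2, 1, 0, -2), 3), c(0.2, 0.5, 0.3))
  path <- tempfile(fileext = ".csv")
  write_prior(pr, path)
  pr2 <- read_prior(path)
  expect_identical(pr2$weights, pr$weights)
  expect_identical(pr2$locations, unname(pr$locations))
  # off-unit weights renormalize with a warning
  df <- utils::read.csv(path)
  df$weight <- df$weight * 0.999999
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(pr3 <- read_prior(path), "renormaliz")
  expect_equal(sum(pr3$weights), 1)
  # negative weights rejected with line numbers
  df$weight[2] <- -0.1
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_prior(path), "line\\(s\\) 3")
  # degenerate single-atom prior is valid
  p1 <- atomic_prior(matrix(c(1, 2), 1), 1)
  write_prior(p1, path)
  expect_equal(nrow(read_prior(path)$locations), 1L)
})
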