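# Shared fixtures, built in code.

fig1_spec <- function() build_preset("fig1")

# tiny single-rate decay model: y = exp(-k t) at one time
one_rate_spec <- function(times = 1, sigma = 0.1) {
  decay_model(1, times = times, noise_sigma = sigma, ordered = FALSE)
}

# a well-separated atomic prior on the 1-d location model: K atoms spaced
# `gap` sigmas apart
spaced_atoms <- function(K, gap, sigma = 1) {
  atomic_prior(matrix(seq(0, by = gap * sigma, length.out = K), ncol = 1))
}

# exact KL between two equal-covariance Gaussians in prediction space
gaussian_kl <- function(spec, theta1, theta2) {
  sum((predict(spec, theta1) - predict(spec, theta2))^2) /
    (2 * spec_sigma(spec)^2)
}

# quadrature D_KL(p(x|theta) || p(x)) for a 1-d observation model with an
# atomic prior: independent oracle by adaptive integration
quad_kl_atomic <- function(spec, theta, prior) {
  sig <- spec_sigma(spec)
  y0 <- predict(spec, theta)
  ys <- drop(infoprior:::predict_matrix(spec, prior$locations))
  f <- function(x) {
    lp <- stats::dnorm(x, y0, sig, log = TRUE)
    lm <- vapply(x, function(xi)
      infoprior:::logsumexp(log(prior$weights) +
                              stats::dnorm(xi, ys, sig, log = TRUE)), 0)
    stats::dnorm(x, y0, sig) * (lp - lm)
  }
  stats::integrate(f, y0 - 12 * sig, y0 + 12 * sig, rel.tol = 1e-9)$value
}
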