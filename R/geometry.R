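# Fisher information geometry.
#
# For additive Gaussian noise the Fisher information metric (FIM) is the
# Euclidean metric on prediction space pulled back through the model
# Jacobian: g = M J^T J / sigma^2, where J_{t,mu} = dy_t / dtheta_mu and M is
# the repetition count.  Its determinant drives the Jeffreys prior, and its
# rank classifies which boundary stratum ("edge") of the model manifold a
# parameter point occupies.

#' Jacobian of the prediction map
#'
#' `J[t, mu] = dy_t / dtheta_mu`.  Analytic for decay models
#' (`dy_t/dtheta_mu = -a_mu t k_mu exp(-k_mu t)` with `k_mu = exp(theta_mu)`);
#' central finite differences (relative step 1e-5) for models solved
#' numerically, such as the enzyme schemes.
#'
#' @param spec a model spec.
#' @param theta parameter vector.
#' @return an `obs_dim x param_dim` matrix.
#' @export
model_jacobian <- function(spec, theta) UseMethod("model_jacobian")

#' @export
model_jacobian.decay_spec <- function(spec, theta) {
  check_theta(spec, theta)
  k <- exp(theta)
  J <- matrix(0, spec$obs_dim, spec$param_dim)
  for (mu in seq_len(spec$param_dim)) {
    J[, mu] <- -spec$amplitudes[mu] * spec$times * k[mu] *
      exp(-k[mu] * spec$times)
  }
  J
}

#' @export
model_jacobian.linear_spec <- function(spec, theta) {
  matrix(1, 1L, 1L)
}

#' @export
model_jacobian.model_spec <- function(spec, theta) {
  check_theta(spec, theta)
  d <- spec$param_dim
  J <- matrix(NA_real_, spec$obs_dim, d)
  for (mu in seq_len(d)) {
    h <- 1e-5 * max(1, abs(theta[mu]))
    tp <- tm <- theta
    tp[mu] <- theta[mu] + h
    tm[mu] <- theta[mu] - h
    J[, mu] <- (predict(spec, tp) - predict(spec, tm)) / (2 * h)
    if (any(!is.finite(J[, mu])))
      stop("non-finite derivative in coordinate ", mu)
  }
  J
}

#' Fisher information metric
#'
#' The metric `g_{mu,nu}(theta) = -E[ d^2 log p(x|theta) / dtheta_mu
#' dtheta_nu ]`.  For Gaussian-noise models this is the pullback
#' `g = M J^T J / sigma^2`; the Bernoulli model uses its exact closed form
#' `1 / (theta (1 - theta))`.
#'
#' @param spec a model spec.
#' @param theta parameter vector.
#' @return object of class `fisher_metric`: a list with elements `matrix`
#'   (d x d, symmetric PSD) and `theta`.
#' @export
fisher_metric <- function(spec, theta) UseMethod("fisher_metric")

#' @export
fisher_metric.model_spec <- function(spec, theta) {
  J <- model_jacobian(spec, theta)
  g <- spec$repetitions * crossprod(J) / spec$noise_sigma^2
  g <- (g + t(g)) / 2
  structure(list(matrix = g, theta = theta), class = "fisher_metric")
}

#' @export
fisher_metric.bernoulli_spec <- function(spec, theta) {
  check_theta(spec, theta)
  g <- matrix(spec$repetitions / (theta * (1 - theta)), 1L, 1L)
  structure(list(matrix = g, theta = theta), class = "fisher_metric")
}

metric_matrix <- function(g) {
  if (inherits(g, "fisher_metric")) g$matrix else as.matrix(g)
}

#' Half log-determinant of a metric
#'
#' `0.5 * log det g`, the log-kernel of the Jeffreys prior, computed by
#' Cholesky decomposition with an eigenvalue fallback.  A singular (PSD but
#' rank-deficient) metric returns `-Inf` flagged with attribute
#' `singular = TRUE`, so samplers naturally avoid measure-zero edges instead
#' of crashing on them.  Asymmetric or indefinite input is rejected.
#'
#' @param g a `fisher_metric` or a symmetric PSD matrix.
#' @export
half_logdet <- function(g) {
  m <- metric_matrix(g)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("metric must be a symmetric matrix")
  ch <- try(chol(m), silent = TRUE)
  if (!inherits(ch, "try-error")) {
    ld <- sum(log(diag(ch)))
    if (is.finite(ld)) return(ld)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 0)
  if (any(ev < -1e-8 * max(scale, 1)))
    stop("metric is not positive semi-definite")
  if (scale == 0 || min(ev) <= 1e-14 * scale)
    return(structure(-Inf, singular = TRUE))
  sum(log(ev)) / 2
}

#' Numerical rank of the Fisher metric
#'
#' Counts eigenvalues above `tol` times the largest eigenvalue.  On the model
#' manifold this is the dimension of the edge a point occupies: interior
#' points have full rank, while boundary strata where parameter directions
#' become indistinguishable lose rank.
#'
#' @param g a `fisher_metric` or symmetric PSD matrix.
#' @param tol relative eigenvalue tolerance.
#' @export
fim_rank <- function(g, tol = 1e-8) {
  ev <- eigen(metric_matrix(g), symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev, 0)
  if (mx <= 0) return(0L)
  sum(ev > tol * mx)
}
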