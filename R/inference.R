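# Posterior computation and the posterior-deviation bias readout.
#
# For a single observation x, the most literal measure of prior-induced bias
# is the distance, in prediction space and in units of the noise width,
# between the maximum-likelihood prediction and the posterior mean
# prediction:
#
#   Delta(x) = || y(theta_hat_x) - E_posterior[ y(theta) ] || / sigma.
#
# An unbiased prior leaves Delta at the order of 1; a prior whose weight is
# concentrated by irrelevant-direction co-volume can pull the posterior mean
# tens of sigma away from the best fit.

#' Maximum likelihood estimate
#'
#' Bounded multistart local optimization of the log-likelihood (L-BFGS-B
#' within the domain box, with the analytic Gaussian-residual gradient where
#' the model Jacobian is analytic).  Ordered domains are handled by sorting,
#' under which the starting points and the returned optimum are projected
#' into the ordered cone.
#'
#' @param spec a model spec.
#' @param x observation vector.
#' @param n_starts number of Latin-hypercube starts (the domain midpoint is
#'   always included).
#' @param seed integer seed for the starts.
#' @return the best theta found, with attribute `logpost` (its
#'   log-likelihood) and `starts` (all starts' achieved values).
#' @export
mle <- function(spec, x, n_starts = 20L, seed = 1L) {
  if (any(!is.finite(x))) stop("x must be finite")
  sortfix <- function(th) if (spec$ordered) sort(th, decreasing = TRUE) else th
  fn <- function(th) -loglikelihood(spec, x, sortfix(th))
  analytic <- inherits(spec, "decay_spec") || inherits(spec, "linear_spec")
  gr <- NULL
  if (analytic) {
    sig <- spec_sigma(spec)
    gr <- function(th) {
      p <- order(th, decreasing = TRUE)
      ths <- if (spec$ordered) th[p] else th
      r <- x - predict(spec, ths)
      g <- -drop(r %*% model_jacobian(spec, ths)) / sig^2
      if (spec$ordered) { gi <- g; gi[p] <- g; g <- gi }
      g
    }
  }
  starts <- with_seed_or_not(seed, rbind(
    (spec$lower + spec$upper) / 2,
    domain_lhs_points(spec, n_starts - 1L)))
  best <- NULL
  vals <- rep(NA_real_, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- try(stats::optim(starts[i, ], fn = fn, gr = gr,
                            method = "L-BFGS-B",
                            lower = spec$lower, upper = spec$upper,
                            control = list(maxit = 200L)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    vals[i] <- -res$value
    if (is.null(best) || -res$value > best$value) {
      best <- list(par = sortfix(res$par), value = -res$value)
    }
  }
  if (is.null(best)) stop("all optimization starts failed")
  structure(best$par, logpost = best$value, starts = vals)
}

#' Exact discrete posterior over the atoms of an atomic prior
#'
#' `p(theta_a | x) \propto w_a p(x | theta_a)`, normalized by log-sum-exp.
#'
#' @param prior an [atomic_prior()].
#' @param spec a model spec.
#' @param x observation vector.
#' @return posterior weight vector over the atoms.
#' @export
posterior_weights <- function(prior, spec, x) {
  ll <- drop(loglik_matrix(spec, matrix(x, nrow = 1L), prior$locations))
  lp <- log(prior$weights) + ll
  exp(lp - logsumexp(lp))
}

resolve_prior_logdensity <- function(spec, prior, ...) {
  if (is.function(prior)) return(list(ld = prior, tag = "custom"))
  if (inherits(prior, "weighted_sample")) {
    if (is.null(prior$logdensity))
      stop("this weighted_sample carries no evaluable log-density")
    return(list(ld = prior$logdensity, tag = prior$source,
                draws = prior$draws))
  }
  if (is.character(prior)) {
    if (prior == "jeffreys")
      return(list(ld = function(th) jeffreys_logdensity(spec, th),
                  tag = "jeffreys"))
    if (prior == "lognormal")
      return(list(ld = function(th) {
        if (!in_domain(spec, th)) return(-Inf)
        lognormal_logdensity(th)
      }, tag = "lognormal"))
    if (prior == "flat")
      return(list(ld = function(th) {
        if (!in_domain(spec, th)) return(-Inf) else 0
      }, tag = "flat"))
  }
  stop("prior must be 'jeffreys', 'lognormal', 'flat', a weighted_sample ",
       "with a log-density, or a function")
}

#' Sample a posterior by adaptive MCMC
#'
#' Targets `log p(x|theta) + log prior(theta)` with the same adaptive
#' random-walk Metropolis engine and diagnostics as [sample_jeffreys()].
#' Chains start from draws of the prior where available (posterior mass
#' tracks prior mass whenever the prior is the dominant factor), otherwise
#' from random domain points, with the MLE added as one extra start.
#'
#' @param spec a model spec.
#' @param x observation vector.
#' @param prior `"jeffreys"`, `"lognormal"`, `"flat"`, a [weighted_sample()]
#'   carrying a log-density, or a log-density function of theta.
#' @param n retained draws.
#' @param seed integer seed.
#' @param n_chains parallel chains.
#' @return a [weighted_sample()] of posterior draws.
#' @export
posterior_sample <- function(spec, x, prior, n = 4000L, seed = 1L,
                             n_chains = 4L) {
  pr <- resolve_prior_logdensity(spec, prior)
  ld <- function(th) {
    lp <- pr$ld(th)
    if (!is.finite(lp)) return(-Inf)
    lp + loglikelihood(spec, x, th)
  }
  res <- with_seed_or_not(seed, {
    init <- if (!is.null(pr$draws)) {
      # start inside the prior mass: when the prior is the dominant factor
      # (the regime where posterior bias matters most) the posterior lives
      # where the prior does, and a maximum-likelihood start would pin a
      # chain in an exponentially subdominant mode
      pr$draws[sample.int(nrow(pr$draws), n_chains), , drop = FALSE]
    } else {
      ini <- find_finite_starts(ld, spec, n_chains)
      th_ml <- try(mle(spec, x, n_starts = 8L,
                       seed = child_seed(seed, 3L)), silent = TRUE)
      if (!inherits(th_ml, "try-error") && is.finite(ld(as.numeric(th_ml))))
        ini[1, ] <- as.numeric(th_ml)
      ini
    }
    bad <- which(!is.finite(apply(init, 1, ld)))
    if (length(bad)) init[bad, ] <- find_finite_starts(ld, spec, length(bad))
    adaptive_metropolis(ld, init, n_keep = n, n_chains = n_chains)
  })
  if (is.finite(res$rhat) && res$rhat > 1.2)
    warning(sprintf("posterior MCMC split-chain Rhat = %.2f > 1.2", res$rhat))
  weighted_sample(res$draws, source = paste0("posterior-", pr$tag),
                  diagnostics = list(acceptance = res$acceptance,
                                     rhat = res$rhat, seed = seed))
}

#' Posterior deviation of the prediction
#'
#' Computes `Delta(x) = || y(theta_hat_x) - E[y | x] || / sigma`, the
#' distance in prediction space (in noise units) between the maximum
#' likelihood prediction and the posterior mean prediction.  The posterior
#' expectation is exact enumeration for atomic priors and MCMC otherwise.
#'
#' @param spec a model spec.
#' @param prior an [atomic_prior()], or anything accepted by
#'   [posterior_sample()].
#' @param x observation vector.
#' @param n MCMC draws for continuous priors.
#' @param seed integer seed.
#' @return a `posterior_report`: list with `theta_hat`, `posterior_y_mean`,
#'   `delta` (units of sigma), `prior_tag` and `diagnostics`.
#' @export
posterior_deviation <- function(spec, prior, x, n = 4000L, seed = 1L) {
  th_hat <- mle(spec, x, seed = child_seed(seed, 11L))
  y_hat <- predict(spec, as.numeric(th_hat))
  if (inherits(prior, "atomic_prior")) {
    pw <- posterior_weights(prior, spec, x)
    Y <- predict_matrix(spec, prior$locations)
    y_mean <- drop(pw %*% Y)
    tag <- "atomic"
    diag <- list(method = "enumeration", K = nrow(prior$locations))
  } else {
    ps <- posterior_sample(spec, x, prior, n = n, seed = seed)
    Y <- predict_matrix(spec, ps$draws)
    y_mean <- colMeans(Y)
    tag <- ps$source
    diag <- ps$diagnostics
  }
  structure(list(theta_hat = as.numeric(th_hat),
                 posterior_y_mean = y_mean,
                 delta = sqrt(sum((y_hat - y_mean)^2)) / spec_sigma(spec),
                 prior_tag = tag, diagnostics = diag),
            class = "posterior_report")
}

#' @export
print.posterior_report <- function(x, ...) {
  cat(sprintf("<posterior_report> prior %s: Delta = %.2f sigma\n",
              x$prior_tag, x$delta))
  invisible(x)
}

#' Effective dimensionality from the information-noise curve
#'
#' Solves for the optimal prior at each noise level in `sigmas` and fits the
#' slope of the optimal mutual information (nats) against `log(1/sigma)`
#' over the last half of the curve.  Along a parameter direction of Fisher
#' length L >> 1 the number of distinguishable points grows like L, and
#' L scales as 1/sigma, so this slope counts the parameter directions the
#' data actually constrain.
#'
#' @param spec a model spec (its `noise_sigma` is replaced per grid point).
#' @param sigmas decreasing vector of at least 3 noise widths.
#' @param seed integer seed.
#' @param ... passed to [optimize_prior()].
#' @return an `info_curve`: list with `sigmas`, `I_bits`, `d_eff`,
#'   `slope_stderr`, `converged` flags and the fitted window.
#' @export
effective_dimension <- function(spec, sigmas, seed = 1L, ...) {
  if (length(sigmas) < 3L || is.unsorted(rev(sigmas), strictly = TRUE))
    stop("sigmas must be a decreasing vector of at least 3 noise widths")
  I_nats <- numeric(length(sigmas))
  conv <- logical(length(sigmas))
  for (i in seq_along(sigmas)) {
    sp <- spec
    sp$noise_sigma <- sigmas[i]
    pr <- optimize_prior(sp, seed = child_seed(seed, i), ...)
    sol <- attr(pr, "solver")
    I_nats[i] <- utils::tail(sol$I_history, 1L)
    conv[i] <- sol$converged
  }
  if (!all(conv))
    warning("optimal-prior solves did not all converge; slope is reported ",
            "with that caveat")
  win <- seq(max(1L, floor(length(sigmas) / 2)), length(sigmas))
  fit <- stats::lm(I_nats[win] ~ log(1 / sigmas[win]))
  structure(list(sigmas = sigmas, I_bits = nats_to_bits(I_nats),
                 I_nats = I_nats,
                 d_eff = unname(stats::coef(fit)[2]),
                 slope_stderr = tryCatch(summary(fit)$coefficients[2, 2],
                                         error = function(e) NA_real_),
                 converged = conv, window = win),
            class = "info_curve")
}

#' @export
print.info_curve <- function(x, ...) {
  cat(sprintf("<info_curve> d_eff = %.2f (se %.2f) over sigma = [%g, %g]\n",
              x$d_eff, x$slope_stderr, max(x$sigmas), min(x$sigmas)))
  invisible(x)
}
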