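# Prior representations and samplers.
#
# Three priors are compared throughout: the Jeffreys prior (proportional to
# sqrt(det g), the invariant volume of the model manifold), a factorized
# log-normal prior on the rates, and the discrete "atomic" prior that
# maximizes the mutual information between parameters and data.  Continuous
# priors are represented by MCMC / direct samples (`weighted_sample`);
# the optimal prior by support points with weights (`atomic_prior`).

#' Atomic prior
#'
#' A discrete prior with `K` weighted support points ("atoms") in parameter
#' space — the representation of the mutual-information-maximizing prior,
#' which is generically discrete.
#'
#' @param locations `K x d` matrix of support points (a vector is taken as a
#'   single d-dimensional atom for d > 1, or K one-dimensional atoms if d is
#'   1-ambiguous; pass a matrix to be explicit).
#' @param weights positive weights; normalized to sum exactly to 1.
#' @return object of class `atomic_prior`.
#' @export
atomic_prior <- function(locations, weights = NULL) {
  if (!is.matrix(locations)) locations <- matrix(locations, ncol = 1L)
  K <- nrow(locations)
  if (K < 1L) stop("an atomic prior needs at least one atom")
  if (is.null(weights)) weights <- rep(1 / K, K)
  if (length(weights) != K) stop("need one weight per atom")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and strictly positive")
  weights <- weights / sum(weights)
  structure(list(locations = locations, weights = weights),
            class = "atomic_prior")
}

#' @export
print.atomic_prior <- function(x, ...) {
  cat(sprintf("<atomic_prior> K = %d atoms in d = %d dimensions\n",
              nrow(x$locations), ncol(x$locations)))
  invisible(x)
}

#' Weighted parameter sample
#'
#' A sample representation of a continuous prior: `n` draws, optional log
#' importance weights (zero for plain MCMC output), a source tag, and an
#' optional evaluable unnormalized log-density (needed by the bridge
#' estimators).
#'
#' @param draws `n x d` matrix.
#' @param logweights log importance weights (default all zero).
#' @param source tag: `"jeffreys"`, `"lognormal"` or `"custom"`.
#' @param logdensity optional function `theta -> unnormalized log-density`.
#' @param diagnostics optional list (acceptance rate, Rhat, ...).
#' @export
weighted_sample <- function(draws, logweights = NULL, source = "custom",
                            logdensity = NULL, diagnostics = list()) {
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  if (is.null(logweights)) logweights <- rep(0, n)
  if (length(logweights) != n) stop("need one logweight per draw")
  lw <- logweights - logsumexp(logweights)
  ess <- exp(-logsumexp(2 * lw))
  structure(list(draws = draws, logweights = logweights, source = source,
                 logdensity = logdensity,
                 diagnostics = c(diagnostics, list(ess = ess, n = n))),
            class = "weighted_sample")
}

#' @export
print.weighted_sample <- function(x, ...) {
  cat(sprintf("<weighted_sample> %d draws in d = %d (source: %s, ESS = %.0f)\n",
              nrow(x$draws), ncol(x$draws), x$source, x$diagnostics$ess))
  if (!is.null(x$diagnostics$rhat))
    cat(sprintf("  acceptance = %.2f, split-chain Rhat = %.3f\n",
                x$diagnostics$acceptance, x$diagnostics$rhat))
  invisible(x)
}

# Normalized weights of a sample prior.
sample_weights <- function(ws) {
  lw <- ws$logweights - logsumexp(ws$logweights)
  exp(lw)
}

#' Jeffreys prior log-density
#'
#' `log sqrt(det g(theta))`, up to the (never computed) additive constant
#' `-log Z`.  Returns `-Inf` outside the domain and at singular points of the
#' metric.  Invariant under experiment repetition: replicating shifts the
#' value by the constant `(d/2) log M`, leaving the normalized prior
#' unchanged.
#'
#' @param spec a model spec.
#' @param theta parameter vector.
#' @export
jeffreys_logdensity <- function(spec, theta) {
  if (!in_domain(spec, theta)) return(-Inf)
  if (!is.null(outcome_support(spec)))
    return(as.numeric(half_logdet(fisher_metric(spec, theta))))
  # For Gaussian pullback metrics, work from the singular values of the
  # Jacobian: sqrt(det g) = prod(s_i / sigma_eff).  Sloppy models have
  # log-spaced Fisher eigenvalues spanning far more decades than det(J'J)
  # survives in double precision, while the singular values themselves are
  # representable.
  J <- model_jacobian(spec, theta)
  s <- svd(J, nu = 0, nv = 0)$d
  if (any(s <= 0) || any(!is.finite(s))) return(structure(-Inf, singular = TRUE))
  sum(log(s)) - spec$param_dim * log(spec_sigma(spec))
}

# Random interior points of the domain box (respecting ordering).
domain_random_points <- function(spec, n) {
  d <- spec$param_dim
  P <- matrix(stats::runif(n * d), n, d)
  P <- sweep(sweep(P, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  if (spec$ordered && d > 1L)
    P <- t(apply(P, 1, sort, decreasing = TRUE))
  P
}

# Latin hypercube fill of the domain box (respecting ordering).
domain_lhs_points <- function(spec, n) {
  d <- spec$param_dim
  P <- lhs::randomLHS(n, d)
  P <- sweep(sweep(P, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  if (spec$ordered && d > 1L)
    P <- t(apply(P, 1, sort, decreasing = TRUE))
  P
}

# Corners of the domain box.  For high d, all 2^d corners are infeasible:
# the two extreme corners plus `n_extra` random sign patterns are used.
domain_corners <- function(spec, max_dim = 6L, n_extra = 40L) {
  d <- spec$param_dim
  if (d <= max_dim) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
  } else {
    signs <- rbind(rep(0, d), rep(1, d),
                   matrix(stats::rbinom(n_extra * d, 1, 0.5), n_extra, d))
  }
  C <- sweep(sweep(signs, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  if (spec$ordered && d > 1L)
    C <- t(apply(C, 1, sort, decreasing = TRUE))
  unique(C)
}

#' Sample the Jeffreys prior by adaptive MCMC
#'
#' Adaptive random-walk Metropolis (4 chains, burn-in 20% of each chain,
#' proposal covariance and scale adapted towards ~0.3 acceptance during
#' burn-in) targeting the unnormalized density `sqrt(det g)` on the domain
#' box.  The acceptance rate and the split-chain Rhat diagnostic are
#' reported; a poor diagnostic raises a warning and is recorded in the
#' output, never silently dropped.
#'
#' @param spec a model spec.
#' @param n number of retained draws (pooled over chains).
#' @param seed integer seed for reproducibility.
#' @param n_chains number of parallel chains (untempered sampler) or
#'   independent replicas (tempered sampler).
#' @param tempered use the parallel-tempered sampler.  Defaults to `TRUE`
#'   for models with 8 or more parameters, whose Jeffreys densities break
#'   single-temperature random walks: chains freeze in narrow local pockets
#'   separated by barriers of tens of nats.
#' @param n_temps,beta_min temperature-ladder geometry for the tempered
#'   sampler.
#' @return a [weighted_sample()] with source `"jeffreys"` and an attached
#'   log-density function.
#' @export
sample_jeffreys <- function(spec, n = 1e5, seed = 1L, n_chains = 4L,
                            tempered = spec$param_dim >= 8L,
                            n_temps = 12L, beta_min = 0.02) {
  ld <- function(theta) jeffreys_logdensity(spec, theta)
  res <- with_seed_or_not(seed, {
    init <- ascent_starts(ld, spec, n_chains)
    if (tempered) {
      tempered_metropolis(ld, init, n_keep = n,
                          n_reps = max(2L, n_chains %/% 2L),
                          n_temps = n_temps, beta_min = beta_min)
    } else {
      adaptive_metropolis(ld, init, n_keep = n, n_chains = n_chains)
    }
  })
  if (is.finite(res$rhat) && res$rhat > 1.2)
    warning(sprintf(
      "Jeffreys MCMC split-chain Rhat = %.2f > 1.2: chains may not have mixed",
      res$rhat))
  weighted_sample(res$draws, source = "jeffreys", logdensity = ld,
                  diagnostics = c(list(acceptance = res$acceptance,
                                       rhat = res$rhat, seed = seed),
                                  res["swap_rate"]))
}

# Chain starting points from short multistart ascents of the target density.
# High-dimensional sloppy targets concentrate on narrow curved ridges whose
# basin a random point may take very long to find; seeding each chain from a
# distinct ascent endpoint puts the mass where it belongs while leaving
# between-basin disagreement visible to the split-Rhat diagnostic.
ascent_starts <- function(ld, spec, n_chains, n_ascent = 2L * n_chains,
                          maxit = NULL) {
  d <- spec$param_dim
  # Nelder-Mead needs iterations proportional to dimension to climb out of
  # the low-density bulk a random point starts in
  maxit <- maxit %||% max(300L, 150L * d)
  cand <- list()
  obj <- function(th) {
    th <- pmin(pmax(th, spec$lower), spec$upper)
    if (spec$ordered && d > 1L) th <- sort(th, decreasing = TRUE)
    v <- ld(th)
    if (!is.finite(v)) 1e10 else -v
  }
  starts <- find_finite_starts(ld, spec, n_ascent)
  for (i in seq_len(n_ascent)) {
    res <- if (d == 1L) {
      try(stats::optim(starts[i, ], obj, method = "Brent",
                       lower = spec$lower, upper = spec$upper),
          silent = TRUE)
    } else {
      try(stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                       control = list(maxit = maxit)), silent = TRUE)
    }
    th <- if (inherits(res, "try-error")) starts[i, ] else res$par
    th <- pmin(pmax(th, spec$lower), spec$upper)
    if (spec$ordered && d > 1L) th <- sort(th, decreasing = TRUE)
    if (is.finite(ld(th)))
      cand[[length(cand) + 1L]] <- list(theta = th, v = ld(th))
  }
  if (!length(cand)) return(starts[seq_len(n_chains), , drop = FALSE])
  cand <- cand[order(vapply(cand, `[[`, 0, "v"), decreasing = TRUE)]
  # drop endpoints whose density is negligible against the best basin found:
  # a chain seeded there spends the whole run climbing instead of sampling
  vs <- vapply(cand, `[[`, 0, "v")
  cand <- cand[vs > vs[1] - 50]
  init <- matrix(NA_real_, n_chains, d)
  for (c_i in seq_len(n_chains)) {
    base <- cand[[((c_i - 1L) %% length(cand)) + 1L]]$theta
    repeat {
      th <- base + stats::rnorm(d, sd = 0.02)
      th <- pmin(pmax(th, spec$lower), spec$upper)
      if (spec$ordered && d > 1L) th <- sort(th, decreasing = TRUE)
      if (is.finite(ld(th))) break
    }
    init[c_i, ] <- th
  }
  init
}

find_finite_starts <- function(ld, spec, n_chains, tries = 400L) {
  d <- spec$param_dim
  starts <- matrix(NA_real_, n_chains, d)
  found <- 0L
  for (i in seq_len(tries)) {
    p <- drop(domain_random_points(spec, 1L))
    if (is.finite(ld(p))) {
      found <- found + 1L
      starts[found, ] <- p
      if (found == n_chains) return(starts)
    }
  }
  stop("could not find starting points with finite density")
}

#' Log-normal prior log-density
#'
#' A prior that is log-normal in each rate constant `k_mu = exp(theta_mu)`,
#' i.e. independent normal in each `theta_mu` with mean `theta_bar` and
#' standard deviation `sigma_bar` (defaults 0 and 1).  Includes the
#' normalizing constant.
#'
#' @param theta parameter vector.
#' @param theta_bar prior mean of each theta coordinate.
#' @param sigma_bar prior standard deviation (> 0).
#' @export
lognormal_logdensity <- function(theta, theta_bar = 0, sigma_bar = 1) {
  if (sigma_bar <= 0) stop("sigma_bar must be > 0")
  sum(stats::dnorm(theta, theta_bar, sigma_bar, log = TRUE))
}

#' Direct sample from the log-normal prior
#'
#' Independent normal draws in theta-space.  Draws falling outside the model
#' domain box (negligible mass for the default box) are redrawn so the sample
#' respects the domain.
#'
#' @param spec a model spec (provides dimension and domain box).
#' @param n number of draws.
#' @param theta_bar,sigma_bar prior location and scale.
#' @param seed integer seed.
#' @export
sample_lognormal <- function(spec, n = 1e4, theta_bar = 0, sigma_bar = 1,
                             seed = 1L) {
  d <- spec$param_dim
  draws <- with_seed_or_not(seed, {
    D <- matrix(stats::rnorm(n * d, theta_bar, sigma_bar), n, d)
    bad <- which(apply(D, 1, function(r)
      any(r < spec$lower) || any(r > spec$upper)))
    for (i in bad) {
      repeat {
        r <- stats::rnorm(d, theta_bar, sigma_bar)
        if (all(r >= spec$lower) && all(r <= spec$upper)) break
      }
      D[i, ] <- r
    }
    D
  })
  if (spec$ordered && d > 1L)
    draws <- t(apply(draws, 1, sort, decreasing = TRUE))
  ld <- function(theta) {
    if (!in_domain(spec, theta)) return(-Inf)
    lognormal_logdensity(theta, theta_bar, sigma_bar) +
      if (spec$ordered) lgamma(d + 1) else 0
  }
  weighted_sample(draws, source = "lognormal", logdensity = ld,
                  diagnostics = list(seed = seed))
}

# ---- prior file I/O ---------------------------------------------------------

#' Write an atomic prior to a CSV file
#'
#' Columns: `weight, theta_1, ..., theta_d`.
#'
#' @param prior an [atomic_prior()].
#' @param path file path.
#' @export
write_prior <- function(prior, path) {
  d <- ncol(prior$locations)
  df <- data.frame(weight = prior$weights, prior$locations)
  names(df) <- c("weight", paste0("theta_", seq_len(d)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an atomic prior from a CSV file
#'
#' Expects the column layout written by [write_prior()].  Weights off from
#' unit sum by more than 1e-8 are renormalized with a warning; malformed rows
#' and negative weights are rejected with their line numbers.
#'
#' @param path file path.
#' @export
read_prior <- function(path) {
  df <- utils::read.csv(path)
  if (!"weight" %in% names(df)) stop("prior file must have a 'weight' column")
  tcols <- grep("^theta_", names(df))
  if (length(tcols) == 0L) stop("prior file must have theta_* columns")
  bad <- which(!stats::complete.cases(df) |
                 apply(df, 1, function(r) any(!is.finite(as.numeric(r)))))
  if (length(bad))
    stop("malformed prior rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  neg <- which(df$weight <= 0)
  if (length(neg))
    stop("non-positive weights at line(s) ",
         paste(neg + 1L, collapse = ", "), " of ", path)
  s <- sum(df$weight)
  if (abs(s - 1) > 1e-8)
    warning(sprintf("prior weights sum to %.10g; renormalizing", s))
  locs <- as.matrix(df[, tcols, drop = FALSE])
  dimnames(locs) <- NULL
  atomic_prior(locs, df$weight)
}
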