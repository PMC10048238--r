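# Adaptive random-walk Metropolis engine shared by the Jeffreys sampler and
# the posterior samplers.
#
# Four parallel chains; during burn-in (20% of each chain) the proposal is
# adapted Haario-style — covariance estimated from the chain history, global
# scale tuned by Robbins-Monro towards ~0.3 acceptance — and then frozen.
# Convergence is monitored with the split-chain Rhat diagnostic; a failure is
# attached to the output as a warning, never silent.

split_rhat <- function(chains) {
  # chains: list of n x d matrices (equal n); returns max over coordinates
  n <- nrow(chains[[1]])
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  segs <- list()
  for (ch in chains) {
    segs <- c(segs, list(ch[seq_len(half), , drop = FALSE],
                         ch[(n - half + 1):n, , drop = FALSE]))
  }
  d <- ncol(chains[[1]])
  rhat <- rep(NA_real_, d)
  for (j in seq_len(d)) {
    xs <- vapply(segs, function(s) mean(s[, j]), 0)
    vs <- vapply(segs, function(s) stats::var(s[, j]), 0)
    W <- mean(vs)
    B <- half * stats::var(xs)
    if (W <= 0) { rhat[j] <- if (B <= 1e-300) 1 else Inf; next }
    rhat[j] <- sqrt(((half - 1) / half * W + B / half) / W)
  }
  max(rhat, na.rm = TRUE)
}

# logdens: function(theta) -> unnormalized log-density (-Inf outside support)
# init: n_chains x d matrix of starting points with finite density
adaptive_metropolis <- function(logdens, init, n_keep,
                                n_chains = nrow(init),
                                burnin_frac = 0.2,
                                target_accept = 0.3,
                                init_scale = NULL) {
  d <- ncol(init)
  keep_per <- ceiling(n_keep / n_chains)
  burn <- max(50L, ceiling(burnin_frac * keep_per / (1 - burnin_frac)))
  draws <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  for (c_i in seq_len(n_chains)) {
    theta <- init[c_i, ]
    lp <- logdens(theta)
    if (!is.finite(lp)) stop("MCMC initial point has zero density")
    ls <- log(init_scale %||% (2.38 / sqrt(d) * 0.5))
    chol_prop <- diag(d)
    run_mean <- theta
    run_cov <- diag(d) * 1e-6
    out <- matrix(NA_real_, keep_per, d)
    n_acc <- 0L; n_tot <- 0L
    total <- burn + keep_per
    for (it in seq_len(total)) {
      z <- stats::rnorm(d)
      prop <- theta + exp(ls) * drop(z %*% chol_prop)
      lp_prop <- logdens(prop)
      accept <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
      if (accept) { theta <- prop; lp <- lp_prop }
      # diminishing adaptation (Haario AM): running covariance throughout,
      # Robbins-Monro scale towards the target acceptance
      ls <- ls + (as.numeric(accept) - target_accept) / it^0.6
      w <- 1 / (it + 1)
      delta <- theta - run_mean
      run_mean <- run_mean + w * delta
      run_cov <- (1 - w) * run_cov + w * tcrossprod(delta)
      if (it >= max(20, 2 * d) && it %% 50 == 0) {
        ch <- try(chol(run_cov + diag(1e-10 * max(diag(run_cov)), d)),
                  silent = TRUE)
        if (!inherits(ch, "try-error")) chol_prop <- ch
      }
      if (it > burn) {
        out[it - burn, ] <- theta
        n_acc <- n_acc + as.integer(accept)
        n_tot <- n_tot + 1L
      }
    }
    draws[[c_i]] <- out
    acc_rates[c_i] <- n_acc / n_tot
  }
  rhat <- split_rhat(draws)
  all_draws <- do.call(rbind, draws)[seq_len(n_keep), , drop = FALSE]
  list(draws = all_draws, acceptance = mean(acc_rates), rhat = rhat,
       n_chains = n_chains, burnin = burn)
}

# Parallel-tempered Metropolis for multimodal ridge targets.
#
# High-dimensional sloppy densities break plain random-walk samplers: chains
# freeze inside narrow local pockets separated by barriers of tens of nats
# and never equilibrate their relative masses.  A geometric temperature
# ladder (beta from 1 down to beta_min) keeps the hottest replica mobile
# across the whole domain while adjacent-temperature swaps percolate states
# down to the cold chain.  Each temperature adapts its own proposal scale
# and covariance (diminishing adaptation).  `n_reps` independent replicas
# feed the split-Rhat diagnostic on the pooled cold draws.
tempered_metropolis <- function(logdens, init, n_keep, n_temps = 12L,
                                beta_min = 0.02, n_reps = 2L,
                                burnin_frac = 0.2, target_accept = 0.3) {
  d <- ncol(init)
  betas <- beta_min^(seq(0, 1, length.out = n_temps))  # betas[1] = 1 (cold)
  keep_per <- ceiling(n_keep / n_reps)
  burn <- max(100L, ceiling(burnin_frac * keep_per / (1 - burnin_frac)))
  total <- burn + keep_per
  reps <- vector("list", n_reps)
  acc <- swap_acc <- 0; acc_n <- swap_n <- 0
  for (r in seq_len(n_reps)) {
    S <- init[rep(seq_len(nrow(init)), length.out = n_temps) , , drop = FALSE]
    S <- S + 0 # copy
    lp <- apply(S, 1, logdens)
    if (any(!is.finite(lp))) stop("tempered MCMC initial points must have finite density")
    ls <- log(2.38 / sqrt(d) * 0.5) + log(1 / sqrt(betas))
    chols <- rep(list(diag(d)), n_temps)
    means <- lapply(seq_len(n_temps), function(i) S[i, ])
    covs <- rep(list(diag(d) * 1e-6), n_temps)
    out <- matrix(NA_real_, keep_per, d)
    for (it in seq_len(total)) {
      for (t_i in seq_len(n_temps)) {
        z <- stats::rnorm(d)
        prop <- S[t_i, ] + exp(ls[t_i]) * drop(z %*% chols[[t_i]])
        lpp <- logdens(prop)
        ok <- is.finite(lpp) &&
          log(stats::runif(1)) < betas[t_i] * (lpp - lp[t_i])
        if (ok) { S[t_i, ] <- prop; lp[t_i] <- lpp }
        if (t_i == 1L) { acc <- acc + as.numeric(ok); acc_n <- acc_n + 1 }
        ls[t_i] <- ls[t_i] + (as.numeric(ok) - target_accept) / it^0.6
        w <- 1 / (it + 1)
        delta <- S[t_i, ] - means[[t_i]]
        means[[t_i]] <- means[[t_i]] + w * delta
        covs[[t_i]] <- (1 - w) * covs[[t_i]] + w * tcrossprod(delta)
        if (it >= max(20, 2 * d) && it %% 50 == 0) {
          ch <- try(chol(covs[[t_i]] +
                           diag(1e-10 * max(diag(covs[[t_i]])), d)),
                    silent = TRUE)
          if (!inherits(ch, "try-error")) chols[[t_i]] <- ch
        }
      }
      # adjacent swaps, alternating even/odd pairs
      off <- it %% 2L
      for (t_i in seq(1L + off, n_temps - 1L, by = 2L)) {
        dl <- (betas[t_i] - betas[t_i + 1L]) * (lp[t_i + 1L] - lp[t_i])
        if (log(stats::runif(1)) < dl) {
          tmp <- S[t_i, ]; S[t_i, ] <- S[t_i + 1L, ]; S[t_i + 1L, ] <- tmp
          tmp <- lp[t_i]; lp[t_i] <- lp[t_i + 1L]; lp[t_i + 1L] <- tmp
          swap_acc <- swap_acc + 1
        }
        swap_n <- swap_n + 1
      }
      if (it > burn) out[it - burn, ] <- S[1L, ]
    }
    reps[[r]] <- out
  }
  rhat <- split_rhat(reps)
  list(draws = do.call(rbind, reps)[seq_len(n_keep), , drop = FALSE],
       acceptance = acc / acc_n, swap_rate = swap_acc / swap_n,
       rhat = rhat, n_chains = n_reps, burnin = burn)
}
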