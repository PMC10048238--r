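# infoprior

Information-optimal priors and bias diagnostics for sloppy models.

## The problem

Mechanistic models in biology and epidemiology — multi-exponential decay
curves, enzyme-kinetics networks, compartment models — are typically
*sloppy*: the eigenvalues of the Fisher information metric

    g(θ) = −E[ ∂² log p(x|θ) ]      (for Gaussian noise: g = J'J/σ²)

span many decades, so only a few parameter directions are constrained by
any realistic experiment.  The Jeffreys prior √det g, the canonical
"uninformative" choice, weights parameter space by *volume* — including the
volume of directions far too thin to observe.  In high dimension that
co-volume varies so wildly that the prior concentrates almost all of its
mass in a small corner of prediction space, and posteriors built from it
are pulled tens of noise standard deviations away from the best fit.

`infoprior` quantifies this failure and constructs the prior that avoids
it.  The central score is the **bias pressure**

    b(θ) = D_KL( p(x|θ) ‖ p(x) ) − I(X;Θ),

the functional derivative of the parameter–data mutual information with
respect to prior weight at θ.  Any prior satisfies E_prior[b] = 0; the
mutual-information-maximizing prior p\*(θ) — generically a *discrete* set of
weighted atoms, the capacity-achieving input distribution of the model seen
as a noisy channel — has b = 0 on its support and worst-case bias
B = max_θ b(θ) equal to zero.  For every other prior B > 0 measures, in
bits, how far it is from unbiased.

The package provides:

* model specs with Gaussian observation noise: multi-exponential decay,
  mass-action enzyme kinetics (Michaelis–Menten and ping-pong mechanisms,
  integrated with `deSolve`), plus simple calibration channels;
* Fisher geometry: analytic/finite-difference Jacobians, metrics, ranks,
  and an underflow-safe Jeffreys log-density built from Jacobian singular
  values;
* adaptive-MCMC samplers for Jeffreys and posterior distributions, direct
  sampling for log-normal priors;
* Monte Carlo estimators of mutual information, KL divergence and bias
  pressure, with paired stochastic lower/upper bounds from an annealed
  Bennett acceptance-ratio bridge;
* a Blahut–Arimoto-style solver for the optimal atomic prior with a
  worst-case-bias convergence certificate;
* posterior-deviation diagnostics Δ(x) and effective-dimensionality curves;
* a config-driven experiment runner (`run_experiment()`) and a thin CLI
  (`inst/cli/infoprior.R`).

## Worked example

Score the Jeffreys prior on the built-in two-rate decay model
(amplitudes 0.8/0.2, observed at t = 1 and 3 with σ = 0.1), then solve for
the optimal prior:

```r
library(infoprior)

spec <- build_preset("fig1")
js   <- sample_jeffreys(spec, n = 2e4, seed = 1)
mi   <- mutual_information(js, spec, n_x = 500, seed = 2,
                           n_outer = 300, n_theta = 4000)
mi
#> <bias_estimate> 1.261 bits (lower 1.261, upper 1.261, se 0.051) [0.874 nats]

B <- worst_case_bias(js, spec, n_x = 2000, seed = 3, mi = mi)
B
#> <bias_estimate> 9.347 bits (lower 9.142, upper 9.347, se 0.479) [6.479 nats]
round(B$theta_star, 2)
#> [1] -6 -6

opt <- optimize_prior(spec, K_init = 40, tol_bits = 0.1, max_iter = 60,
                      n_x = 800, seed = 2)
attr(opt, "solver")$B
#> <bias_estimate> 0.060 bits (lower 0.060, upper 0.060, se 0.019) [0.041 nats]
nats_to_bits(tail(attr(opt, "solver")$I_history, 1))
#> [1] 2.316273
```

Reading: the Jeffreys prior exposes about 1.3 bits of the model's
behavior to this experiment, but carries a worst-case bias of ~10 bits,
attained where both decay rates are slow (θ\* at the slow-rate corner, the
effectively one-dimensional sliver of prediction space that the volume
measure starves).  The solved atomic prior captures 2.3 bits — nearly a
bit more — and its worst-case bias certificate is below a tenth of a bit,
zero up to the numerical error of the search.

Per-observation bias readout:

```r
x  <- simulate_observation(spec, log(c(1, 0.3)), seed = 7)
posterior_deviation(spec, js, x, seed = 8)     # Jeffreys posterior, MCMC
posterior_deviation(spec, opt, x, seed = 8)    # atomic posterior, exact
```

Config-driven runs (`key = value` files) write reproducible JSON/CSV
bundles:

```sh
Rscript inst/cli/infoprior.R presets
Rscript inst/cli/infoprior.R run my_experiment.txt --out-dir results/run1
```

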