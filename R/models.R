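# Generative models: differentiable prediction maps y(theta) with additive
# Gaussian observation noise, plus a discrete-outcome Bernoulli model used as
# an analytically tractable reference channel.
#
# A model spec bundles the prediction map, the noise scale sigma, the
# parameter domain (a finite box, optionally restricted to the ordered cone
# theta_1 >= theta_2 >= ... when parameters are exchangeable), and a
# repetition count M.  Repeating an experiment M times multiplies the Fisher
# information by M, which for Gaussian noise is identical to shrinking the
# noise to sigma / sqrt(M); all likelihood computations therefore use the
# effective noise returned by `spec_sigma()`.

new_model_spec <- function(subclass, param_dim, obs_dim, noise_sigma,
                           lower, upper, ordered = FALSE, repetitions = 1L,
                           ...) {
  stopifnot(param_dim >= 1, obs_dim >= 1)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma <= 0)
    stop("noise_sigma must be a single positive number")
  repetitions <- as.integer(repetitions)
  if (is.na(repetitions) || repetitions < 1L)
    stop("repetitions must be an integer >= 1")
  lower <- rep_len(lower, param_dim)
  upper <- rep_len(upper, param_dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("domain must be a finite box with lower < upper")
  structure(
    list(param_dim = as.integer(param_dim), obs_dim = as.integer(obs_dim),
         noise_sigma = noise_sigma, lower = lower, upper = upper,
         ordered = isTRUE(ordered), repetitions = repetitions, ...),
    class = c(subclass, "model_spec"))
}

#' Multi-exponential decay model
#'
#' The mean signal at time `t` is a sum of decaying exponentials,
#' `y_t = sum_mu a_mu * exp(-k_mu * t)`, observed with additive Gaussian noise
#' of constant width `sigma`.  Rates are parametrized on the log scale,
#' `theta_mu = log k_mu`, so the parameter domain is a finite box in theta.
#' When all amplitudes are equal the model is invariant under permutations of
#' the rates; the canonical domain then orders them `k_1 >= k_2 >= ...`
#' (`ordered = TRUE`).
#'
#' @param amplitudes nonnegative amplitude vector `a` (its length sets the
#'   parameter dimension `d`); defaults sum to 1 so that `y_0 = 1`.
#' @param times strictly increasing positive observation times.
#' @param noise_sigma Gaussian noise width.
#' @param domain length-2 vector giving common per-coordinate bounds on
#'   `theta = log k`, or a 2-column matrix of per-coordinate bounds.
#' @param ordered impose the ordering constraint `theta_1 >= theta_2 >= ...`.
#' @param repetitions number of independent repetitions `M` of the experiment.
#' @return an object of class `c("decay_spec", "model_spec")`.
#' @examples
#' spec <- decay_model(c(0.8, 0.2), times = c(1, 3))
#' predict(spec, theta = log(c(2, 1)))
#' @export
decay_model <- function(amplitudes, times, noise_sigma = 0.1,
                        domain = c(-6, 6), ordered = TRUE, repetitions = 1L) {
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be nonnegative and strictly increasing")
  d <- length(amplitudes)
  if (is.matrix(domain)) {
    lower <- domain[, 1]; upper <- domain[, 2]
  } else {
    lower <- domain[1]; upper <- domain[2]
  }
  new_model_spec("decay_spec", d, length(times), noise_sigma, lower, upper,
                 ordered = ordered, repetitions = repetitions,
                 amplitudes = as.numeric(amplitudes), times = as.numeric(times))
}

#' One-parameter linear-Gaussian location model
#'
#' `y = theta` observed once with Gaussian noise: the simplest model with a
#' constant Fisher metric.  Used as a calibration target for samplers and
#' information estimators, whose exact answers are available in closed form
#' or by one-dimensional quadrature.
#'
#' @param noise_sigma Gaussian noise width.
#' @param domain length-2 interval for theta.
#' @export
linear_model <- function(noise_sigma = 1, domain = c(0, 1)) {
  new_model_spec("linear_spec", 1L, 1L, noise_sigma,
                 domain[1], domain[2], ordered = FALSE)
}

#' Single-flip Bernoulli model
#'
#' One observation `x` in \{0, 1\} with `P(x = 1 | theta) = theta`.  The one
#' model whose mutual-information-maximizing prior is known analytically:
#' atoms at theta = 0 and 1 with equal weight, achieving exactly 1 bit.
#' Outcomes are enumerable, so all information quantities for this model are
#' computed exactly rather than by Monte Carlo.
#'
#' @export
bernoulli_model <- function() {
  # noise_sigma is only used as the prediction-space merge scale for atoms
  new_model_spec("bernoulli_spec", 1L, 1L, noise_sigma = 0.5,
                 lower = 0, upper = 1, ordered = FALSE)
}

#' Mass-action enzyme kinetics model
#'
#' Two reaction schemes are available.  `"mm3"` is the three-rate mechanism
#' E + S <=> ES -> E + P (rates kf, kr, kp), observing the product
#' concentration `[P]`.  `"pingpong8"` is the eight-rate ping-pong mechanism
#' E + A -> EA <=> E*P -> E* + P followed by E* + B -> E*B <=> EQ -> E + Q,
#' observing the final product `[Q]`.  Rate constants are parametrized as
#' `k_i = exp(theta_i)` and the mass-action ODEs are integrated with a
#' stiff-capable solver at tight tolerance so that integration error is
#' negligible against the observation noise.
#'
#' @param scheme `"mm3"` or `"pingpong8"`.
#' @param times observation times.
#' @param noise_sigma Gaussian noise width on the observed concentration.
#' @param init named vector of initial concentrations; defaults start all
#'   complexes and products at zero with unit enzyme and substrate(s).
#' @param observed name of the observed species (`"P"` for mm3, `"Q"` for
#'   pingpong8).
#' @param domain bounds on theta = log k.
#' @param rtol,atol solver tolerances.
#' @param repetitions number of repetitions M.
#' @export
enzyme_model <- function(scheme = c("mm3", "pingpong8"), times,
                         noise_sigma = 0.1, init = NULL, observed = NULL,
                         domain = c(-6, 6), rtol = 1e-8, atol = 1e-10,
                         repetitions = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "mm3") {
    species <- c("E", "S", "ES", "P")
    default_init <- c(E = 1, S = 1, ES = 0, P = 0)
    d <- 3L
    observed <- observed %||% "P"
  } else {
    species <- c("E", "A", "EA", "EsP", "Es", "P", "B", "EsB", "EQ", "Q")
    default_init <- c(E = 1, A = 1, EA = 0, EsP = 0, Es = 0, P = 0,
                      B = 1, EsB = 0, EQ = 0, Q = 0)
    d <- 8L
    observed <- observed %||% "Q"
  }
  if (is.null(init)) init <- default_init
  if (!all(species %in% names(init)))
    stop("init must name all species: ", paste(species, collapse = ", "))
  if (any(init < 0)) stop("initial concentrations must be nonnegative")
  if (!observed %in% species) stop("observed species must be one of: ",
                                   paste(species, collapse = ", "))
  new_model_spec("enzyme_spec", d, length(times), noise_sigma,
                 domain[1], domain[2], ordered = FALSE,
                 repetitions = repetitions,
                 scheme = scheme, species = species,
                 init = init[species], observed = observed,
                 times = as.numeric(times), rtol = rtol, atol = atol)
}

# ---- domain -----------------------------------------------------------------

#' Effective noise width of a spec
#'
#' Returns `noise_sigma / sqrt(repetitions)`: repeating a Gaussian-noise
#' experiment M times is exactly equivalent to a single observation with the
#' noise shrunk by sqrt(M).
#'
#' @param spec a model spec.
#' @export
spec_sigma <- function(spec) spec$noise_sigma / sqrt(spec$repetitions)

#' Replicate an experiment
#'
#' Returns a spec describing `M` independent repetitions of the experiment.
#' The Fisher metric of the result is exactly `M` times the original's at
#' every theta.
#'
#' @param spec a model spec.
#' @param M integer number of repetitions (>= 1).
#' @export
replicate_spec <- function(spec, M) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be an integer >= 1")
  spec$repetitions <- spec$repetitions * M
  spec
}

#' Is theta inside the model domain?
#'
#' Checks the finite box bounds and, for ordered specs, the constraint
#' `theta_1 >= theta_2 >= ...`.
#'
#' @param spec a model spec.
#' @param theta parameter vector.
#' @export
in_domain <- function(spec, theta) {
  if (length(theta) != spec$param_dim || any(!is.finite(theta))) return(FALSE)
  if (any(theta < spec$lower - 1e-12) || any(theta > spec$upper + 1e-12))
    return(FALSE)
  if (spec$ordered && spec$param_dim > 1L && any(diff(theta) > 1e-12))
    return(FALSE)
  TRUE
}

check_theta <- function(spec, theta) {
  if (!is.numeric(theta) || length(theta) != spec$param_dim)
    stop("theta must be a numeric vector of length ", spec$param_dim)
  if (any(!is.finite(theta)))
    stop("theta must be finite")
  invisible(theta)
}

# ---- prediction -------------------------------------------------------------

#' Model predictions
#'
#' Evaluates the noise-free prediction map `y(theta)`, an `obs_dim`-vector.
#'
#' @param object a model spec.
#' @param theta parameter vector inside the domain.
#' @param ... unused.
#' @return numeric vector of length `obs_dim`.
#' @export
predict.model_spec <- function(object, theta, ...) {
  check_theta(object, theta)
  drop(predict_matrix(object, matrix(theta, nrow = 1L)))
}

# Vectorized prediction: Theta is n x d, result n x m.
predict_matrix <- function(spec, Theta) UseMethod("predict_matrix")

#' @export
predict_matrix.decay_spec <- function(spec, Theta) {
  K <- exp(Theta)                       # n x d rate constants
  Y <- matrix(0, nrow(Theta), spec$obs_dim)
  for (mu in seq_len(spec$param_dim)) {
    Y <- Y + spec$amplitudes[mu] * exp(-outer(K[, mu], spec$times))
  }
  Y
}

#' @export
predict_matrix.linear_spec <- function(spec, Theta) {
  matrix(Theta[, 1], ncol = 1L)
}

#' @export
predict_matrix.bernoulli_spec <- function(spec, Theta) {
  matrix(Theta[, 1], ncol = 1L)        # mean of x
}

#' @export
predict_matrix.enzyme_spec <- function(spec, Theta) {
  Y <- matrix(NA_real_, nrow(Theta), spec$obs_dim)
  for (i in seq_len(nrow(Theta))) Y[i, ] <- enzyme_solve(spec, Theta[i, ])
  Y
}

enzyme_rhs_mm3 <- function(t, y, k) {
  v_f <- k[1] * y["E"] * y["S"]; v_r <- k[2] * y["ES"]; v_p <- k[3] * y["ES"]
  list(c(E = -v_f + v_r + v_p,
         S = -v_f + v_r,
         ES = v_f - v_r - v_p,
         P = v_p))
}

enzyme_rhs_pingpong8 <- function(t, y, k) {
  r1 <- k[1] * y["E"] * y["A"]
  r2 <- k[2] * y["EA"];  r3 <- k[3] * y["EsP"]
  r4 <- k[4] * y["EsP"]
  r5 <- k[5] * y["Es"] * y["B"]
  r6 <- k[6] * y["EsB"]; r7 <- k[7] * y["EQ"]
  r8 <- k[8] * y["EQ"]
  list(c(E = -r1 + r8,
         A = -r1,
         EA = r1 - r2 + r3,
         EsP = r2 - r3 - r4,
         Es = r4 - r5,
         P = r4,
         B = -r5,
         EsB = r5 - r6 + r7,
         EQ = r6 - r7 - r8,
         Q = r8))
}

# Integrate the mass-action system and return the observed species at the
# requested times.  Solver failures raise an explicit error rather than
# propagating NaN into likelihoods.
enzyme_solve <- function(spec, theta, full = FALSE) {
  check_theta(spec, theta)
  k <- exp(theta)
  rhs <- if (spec$scheme == "mm3") enzyme_rhs_mm3 else enzyme_rhs_pingpong8
  tout <- sort(unique(c(0, spec$times)))
  sol <- try(deSolve::lsoda(y = spec$init, times = tout, func = rhs,
                            parms = k, rtol = spec$rtol, atol = spec$atol),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(tout) ||
      any(!is.finite(sol[, -1])))
    stop("enzyme ODE integration failed for theta = (",
         paste(signif(theta, 4), collapse = ", "), ")")
  rows <- match(spec$times, sol[, "time"])
  if (full) return(sol[rows, spec$species, drop = FALSE])
  unname(sol[rows, spec$observed])
}

# ---- likelihood -------------------------------------------------------------

#' Gaussian log-likelihood
#'
#' For Gaussian-noise models, `log p(x | theta) = -||x - y(theta)||^2 /
#' (2 sigma_eff^2) - (m/2) log(2 pi sigma_eff^2)` with `sigma_eff =
#' sigma / sqrt(M)`.  The Bernoulli model implements its own discrete mass
#' function.
#'
#' @param spec a model spec.
#' @param x observation vector of length `obs_dim`.
#' @param theta parameter vector.
#' @return scalar log-density.
#' @export
loglikelihood <- function(spec, x, theta) {
  if (length(x) != spec$obs_dim)
    stop("x must have length obs_dim = ", spec$obs_dim)
  if (any(!is.finite(x))) stop("x must be finite")
  check_theta(spec, theta)
  drop(loglik_matrix(spec, matrix(x, nrow = 1L), matrix(theta, nrow = 1L)))
}

# n x K matrix of log p(x_i | theta_a): rows index observations X (n x m),
# columns index parameter points Theta (K x d).
loglik_matrix <- function(spec, X, Theta) UseMethod("loglik_matrix")

#' @export
loglik_matrix.model_spec <- function(spec, X, Theta) {
  sig <- spec_sigma(spec)
  Y <- predict_matrix(spec, Theta)
  -cross_sqdist(X, Y) / (2 * sig^2) -
    (spec$obs_dim / 2) * log(2 * pi * sig^2)
}

#' @export
loglik_matrix.bernoulli_spec <- function(spec, X, Theta) {
  th <- Theta[, 1]
  x <- X[, 1]
  # handle theta in {0,1} exactly: log(0)*0 := 0 at the matching outcome
  l1 <- matrix(log(th), nrow(X), length(th), byrow = TRUE)
  l0 <- matrix(log1p(-th), nrow(X), length(th), byrow = TRUE)
  out <- x * l1 + (1 - x) * l0
  out[x == 1, ] <- l1[x == 1, , drop = FALSE]
  out[x == 0, ] <- l0[x == 0, , drop = FALSE]
  out
}

# ---- outcome enumeration (discrete models) ----------------------------------

# For models with finitely many outcomes, information quantities are computed
# by exact summation.  Returns NULL for continuous models.
outcome_support <- function(spec) UseMethod("outcome_support")
#' @export
outcome_support.model_spec <- function(spec) NULL
#' @export
outcome_support.bernoulli_spec <- function(spec) matrix(c(0, 1), ncol = 1L)

# ---- simulation -------------------------------------------------------------

# n x m matrix of draws x ~ p(. | theta), using the ambient RNG stream.
simulate_matrix <- function(spec, theta, n) UseMethod("simulate_matrix")

#' @export
simulate_matrix.model_spec <- function(spec, theta, n) {
  y <- predict(spec, theta)
  sig <- spec_sigma(spec)
  matrix(y, n, spec$obs_dim, byrow = TRUE) +
    sig * matrix(stats::rnorm(n * spec$obs_dim), n, spec$obs_dim)
}

#' @export
simulate_matrix.bernoulli_spec <- function(spec, theta, n) {
  matrix(as.numeric(stats::runif(n) < theta[1]), ncol = 1L)
}

#' Simulate an observation
#'
#' Draws `x = y(theta) + sigma_eff * z` with standard normal `z`
#' (or the model's own sampling rule for discrete models), reproducibly
#' under `seed`.
#'
#' @param spec a model spec.
#' @param theta parameter vector inside the domain.
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @param n number of draws; the default 1 returns a vector, larger `n`
#'   an `n x obs_dim` matrix.
#' @export
simulate_observation <- function(spec, theta, seed = NULL, n = 1L) {
  check_theta(spec, theta)
  if (!in_domain(spec, theta)) stop("theta outside the model domain")
  X <- with_seed_or_not(seed, simulate_matrix(spec, theta, n))
  if (n == 1L) drop(X) else X
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<%s> d = %d parameters, m = %d observations, sigma = %g",
              class(x)[1], x$param_dim, x$obs_dim, x$noise_sigma))
  if (x$repetitions > 1L) cat(sprintf(", M = %d repetitions", x$repetitions))
  if (x$ordered) cat(", ordered rates")
  cat("\n")
  invisible(x)
}
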