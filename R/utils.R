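# Numerical helpers shared across modules.

#' Log-sum-exp of a vector
#'
#' Computes `log(sum(exp(v)))` without overflow.  Returns `-Inf` for an
#' all-`-Inf` input (an empty mixture), never `NaN`.
#'
#' @param v numeric vector.
#' @return scalar.
#' @keywords internal
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Row-wise log-sum-exp of a matrix, safe for rows containing -Inf.
row_logsumexp <- function(M) {
  if (!is.matrix(M)) M <- matrix(M, nrow = 1L)
  idx <- max.col(M, ties.method = "first")
  mx <- M[cbind(seq_len(nrow(M)), idx)]
  out <- mx + log(rowSums(exp(M - mx)))
  bad <- !is.finite(mx)
  out[bad] <- mx[bad]
  out
}

# Squared Euclidean cross-distances between the rows of X (n x m) and the
# rows of Y (K x m); returns n x K.  Clamped at zero against round-off.
cross_sqdist <- function(X, Y) {
  n <- nrow(X); K <- nrow(Y)
  d2 <- matrix(rowSums(X^2), n, K) +
    matrix(rowSums(Y^2), n, K, byrow = TRUE) -
    2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  d2
}

#' Convert nats to bits
#' @param x value in nats.
#' @return value in bits.
#' @export
nats_to_bits <- function(x) x / log(2)

# Derive a child seed from a base seed; kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; a NULL seed runs in the ambient stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
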