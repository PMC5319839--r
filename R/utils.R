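# Small internal helpers shared across modules.

#' @importFrom stats rnorm rpois runif quantile var sd lm coef
#' @importFrom methods new validObject is slot
NULL

# Euclidean norm of a 2-vector (or columns of a 2 x n matrix).
vecNorm <- function(v) {
  if (is.matrix(v)) sqrt(colSums(v^2)) else sqrt(sum(v^2))
}

unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < .Machine$double.eps) c(0, 0) else v / n
}

# Angle (degrees, in [0, 180]) between two 2-vectors; NA if either is ~0.
angleBetween <- function(a, b) {
  na <- vecNorm(a); nb <- vecNorm(b)
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

clampPoint <- function(p, bounds) {
  # bounds = c(xmin, ymin, xmax, ymax)
  c(min(max(p[1], bounds[1]), bounds[3]),
    min(max(p[2], bounds[2]), bounds[4]))
}

# Derive a child seed from a base seed and a stream index, staying well
# below .Machine$integer.max.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009) %% 2147483587L) + 1L
}

# Log-density of a multivariate normal via Cholesky (no external dep).
dmvnormLog <- function(x, mean, sigma) {
  L <- chol(sigma)
  d <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * sum(d^2) - sum(log(diag(L))) - 0.5 * length(x) * log(2 * pi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
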