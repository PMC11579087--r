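# Numeric helpers shared across modules. Several of these must stay
# complex-analytic: gradients elsewhere in the package are computed by
# complex-step differentiation, so branching may only depend on Re(x)
# (locally constant branches preserve analyticity).

#' Numerically safe softplus
#'
#' `log(1 + exp(x))` without overflow for large `x`. Accepts complex input
#' (branch chosen on the real part) so that complex-step derivatives pass
#' through unchanged.
#'
#' @param x numeric or complex vector.
#' @return vector of the same mode as `x`.
#' @export
softplus <- function(x) {
  big <- Re(x) > 30
  out <- x
  out[!big] <- log(1 + exp(x[!big]))
  # for large x, softplus(x) = x + log1p(exp(-x)) ~= x up to < 1e-13
  out[big] <- x[big] + exp(-x[big])
  out
}

#' Inverse of the softplus transform
#'
#' @param y positive numeric vector.
#' @return `x` with `softplus(x) = y`.
#' @export
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

# derivative of softplus = logistic sigmoid
sigmoid <- function(x) {
  pos <- Re(x) >= 0
  out <- x
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# swish activation and its derivative (hidden layers of branch networks)
swish <- function(x) x * sigmoid(x)
swish_grad <- function(x) {
  s <- sigmoid(x)
  s + x * s * (1 - s)
}

# Step size for complex-step differentiation. The objective code is written
# to be complex-analytic, so the step can be taken far below sqrt(eps)
# without subtractive cancellation.
CSTEP <- 1e-100

# d f / d x via a single complex evaluation; f must be analytic.
complex_step <- function(f, x, h = CSTEP) {
  Im(f(x + h * 1i)) / h
}

# rowsum() that tolerates complex input (used when accumulating per-dose
# contributions under an active complex-step perturbation).
rowsum_c <- function(x, group, ngroups) {
  if (length(x) == 0L) {
    return(if (is.complex(x)) complex(ngroups) else numeric(ngroups))
  }
  if (is.complex(x)) {
    m <- rowsum(cbind(Re(x), Im(x)), group)
    full <- complex(ngroups)
    full[as.integer(rownames(m))] <- complex(real = m[, 1], imaginary = m[, 2])
  } else {
    m <- rowsum(x, group)
    full <- numeric(ngroups)
    full[as.integer(rownames(m))] <- m[, 1]
  }
  full
}

# log density of N(x; 0, Sigma) via Cholesky (hand-rolled, K small)
log_dmvnorm0 <- function(x, sigma) {
  ch <- chol(sigma)
  u <- backsolve(ch, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(u^2)
}

# draws from N(0, Sigma); n x K matrix
rmvnorm0 <- function(n, sigma) {
  k <- nrow(sigma)
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% chol(sigma)
}

# symmetric positive-semidefinite matrix square root (small matrices)
sqrtm_psd <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

is_pd <- function(m, tol = 1e-12) {
  if (any(!is.finite(m))) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1e-300))
}

# round half away from zero (dose rounding convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# deterministic child seeds below 2^31, derived from a master seed
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
  as.integer(s)
}
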