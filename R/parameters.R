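# Population-parameter containers Theta = {theta, Omega, Sigma} and their
# unconstrained ("raw") vector representation used by the optimizers.
# Variance-like quantities are kept positive through softplus and the
# random-effect correlation is kept in (-1, 1) through tanh; training and
# trailing-window averaging act on the raw scale.

#' Residual error model
#'
#' Observation noise is Gaussian with variance
#' `sigma_add^2 + (sigma_prop * yhat)^2` (the proportional term uses the
#' model prediction, the usual pharmacometric convention). `kind =
#' "additive"` fixes `sigma_prop = 0`.
#'
#' @param kind `"additive"` or `"combined"`.
#' @param sigma_add additive SD (IU/dL, >= 0).
#' @param sigma_prop proportional SD (dimensionless, >= 0).
#' @return a `residual_model` object.
#' @export
residual_model <- function(kind = c("additive", "combined"),
                           sigma_add = 5, sigma_prop = 0) {
  kind <- match.arg(kind)
  if (kind == "additive") sigma_prop <- 0
  if (sigma_add < 0 || sigma_prop < 0 || (sigma_add == 0 && sigma_prop == 0)) {
    stop("residual_model: need sigma_add, sigma_prop >= 0 with at least one > 0")
  }
  structure(list(kind = kind, sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "residual_model")
}

#' Random-effect covariance in S C S' form
#'
#' The covariance `Omega` is decomposed into marginal standard deviations
#' `S` and a correlation matrix `C` such that `Omega = S C S'`.
#'
#' @param S vector of positive marginal SDs (length K, K <= 2 supported).
#' @param C K x K correlation matrix (symmetric, unit diagonal, PD).
#' @return an `omega_decomposition` object.
#' @export
omega_decomposition <- function(S, C = diag(length(S))) {
  K <- length(S)
  stopifnot(K >= 1, K <= 2, all(S > 0), nrow(C) == K, ncol(C) == K)
  if (any(abs(diag(C) - 1) > 1e-12) || max(abs(C - t(C))) > 1e-12) {
    stop("omega_decomposition: C must be symmetric with unit diagonal")
  }
  if (!is_pd(C)) stop("omega_decomposition: correlation matrix is not positive definite")
  structure(list(S = as.numeric(S), C = unname(C)), class = "omega_decomposition")
}

#' Covariance matrix implied by an omega_decomposition
#'
#' @param omega an [omega_decomposition()] or a plain matrix (returned
#'   unchanged).
#' @return the K x K covariance matrix `S C S'`.
#' @export
omega_matrix <- function(omega) {
  if (is.matrix(omega)) return(omega)
  diag(omega$S, length(omega$S)) %*% omega$C %*% diag(omega$S, length(omega$S))
}

# decomposition from a covariance matrix
omega_from_matrix <- function(m) {
  s <- sqrt(diag(m))
  omega_decomposition(s, stats::cov2cor(m))
}

#' Population parameters Theta
#'
#' Bundles the fixed-effects object (network or truth map), the
#' random-effect covariance and the residual-error model. For conjugate
#' toy models a custom prediction function can be supplied instead of the
#' PK model: `predfun(subject, eta)` returning `list(y = predictions,
#' G = d y / d eta)` (it must accept complex `eta` for derivative checks).
#'
#' @param theta fixed effects: a `dcm_network`, `dcm_truth`, or `NULL`
#'   for toy models.
#' @param omega an [omega_decomposition()].
#' @param residual a [residual_model()].
#' @param predfun optional toy prediction function (see Details).
#' @return a `population_parameters` object.
#' @export
population_parameters <- function(theta, omega, residual, predfun = NULL) {
  stopifnot(inherits(omega, "omega_decomposition"),
            inherits(residual, "residual_model"))
  structure(list(theta = theta, omega = omega, residual = residual,
                 predfun = predfun, K = length(omega$S)),
            class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("<population_parameters> K =", x$K,
      "| residual:", x$residual$kind,
      sprintf("(sigma_add = %.3g, sigma_prop = %.3g)\n",
              x$residual$sigma_add, x$residual$sigma_prop))
  cat("  omega S:", signif(x$omega$S, 4), "\n")
  invisible(x)
}

# ---- raw (unconstrained) parameter vector -----------------------------
# layout: [network weights | u_S (K) | u_rho (K==2) | u_sig_add | u_sig_prop]
# the trailing residual entries are present according to the error model.

raw_layout <- function(pop) {
  nnet <- if (inherits(pop$theta, "dcm_network")) length(net_pack(pop$theta)) else 0L
  K <- pop$K
  nrho <- if (K == 2) 1L else 0L
  nsig <- if (pop$residual$kind == "combined") 2L else 1L
  list(nnet = nnet, K = K, nrho = nrho, nsig = nsig,
       total = nnet + K + nrho + nsig)
}

pop_to_raw <- function(pop) {
  lay <- raw_layout(pop)
  raw <- numeric(0)
  if (lay$nnet) raw <- net_pack(pop$theta)
  raw <- c(raw, softplus_inv(pop$omega$S))
  if (lay$nrho) raw <- c(raw, atanh(pop$omega$C[1, 2]))
  raw <- c(raw, softplus_inv(pop$residual$sigma_add))
  if (lay$nsig == 2) raw <- c(raw, softplus_inv(pop$residual$sigma_prop))
  raw
}

pop_from_raw <- function(raw, skeleton) {
  pop <- skeleton
  lay <- raw_layout(skeleton)
  pos <- 0L
  if (lay$nnet) {
    pop$theta <- net_unpack(raw[seq_len(lay$nnet)], skeleton$theta)
    pos <- lay$nnet
  }
  S <- softplus(raw[pos + seq_len(lay$K)]); pos <- pos + lay$K
  C <- diag(lay$K)
  if (lay$nrho) {
    rho <- tanh(raw[pos + 1L]); pos <- pos + 1L
    C[1, 2] <- C[2, 1] <- rho
  }
  pop$omega <- omega_decomposition(S, C)
  sa <- softplus(raw[pos + 1L]); pos <- pos + 1L
  sp <- if (lay$nsig == 2) softplus(raw[pos + 1L]) else 0
  pop$residual <- residual_model(skeleton$residual$kind, sa, sp)
  pop
}

# variance pieces straight from the raw tail (complex-capable; used by the
# vectorized objectives under complex-step perturbations)
var_from_raw <- function(raw, lay) {
  pos <- lay$nnet
  s1 <- softplus(raw[pos + 1L])
  s2 <- if (lay$K == 2) softplus(raw[pos + 2L]) else NULL
  pos <- pos + lay$K
  rho <- if (lay$nrho) tanh(raw[pos + 1L]) else NULL
  pos <- pos + lay$nrho
  siga <- softplus(raw[pos + 1L])
  sigp <- if (lay$nsig == 2) softplus(raw[pos + 2L]) else 0
  list(s1 = s1, s2 = s2, rho = rho, siga = siga, sigp = sigp)
}
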