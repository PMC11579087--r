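# Training objectives over the population model: MSE, FO, FOCE (with the
# per-subject MAP inner step) and the reparametrized ELBO for VI. These
# are the reference (per-subject) implementations; dcm_fit() uses an
# algebraically identical vectorized path (objectives-fast.R) whose
# agreement with these functions is asserted in the test suite.

# Subject prediction and d y / d eta at a given eta. For the PK model the
# derivative uses the closed-form sensitivities of the two-compartment
# solution; for toy models the user-supplied predfun provides both.
predict_eta <- function(pop, subject, eta) {
  if (!is.null(pop$predfun)) return(pop$predfun(subject, eta))
  zeta <- typical_params(pop$theta, data.frame(weight = subject$covariates$weight,
                                               vwf = subject$covariates$vwf))
  z_CL <- zeta$CL[1] * exp(eta[1])
  z_V1 <- zeta$V1[1] * exp(eta[2])
  nt <- length(subject$obs_times)
  nd <- nrow(subject$doses)
  if (nt == 0L) {
    return(list(y = numeric(0), G = matrix(0, 0, 2)))
  }
  if (nd == 0L) {
    return(list(y = numeric(nt), G = matrix(0, nt, 2)))
  }
  it <- rep(seq_len(nt), times = nd)
  id <- rep(seq_len(nd), each = nt)
  r <- pk_conc_pairs(rep(z_CL, nt * nd), rep(z_V1, nt * nd),
                     rep(zeta$Q[1], nt * nd), rep(zeta$V2[1], nt * nd),
                     subject$doses$time[id], subject$doses$amount[id],
                     subject$doses$duration[id], subject$obs_times[it],
                     grad = TRUE)
  y <- rowsum_c(r$c, it, nt)
  dCL <- rowsum_c(r$dCL, it, nt)
  dV1 <- rowsum_c(r$dV1, it, nt)
  list(y = y, G = cbind(z_CL * dCL, z_V1 * dV1))
}

resid_variance <- function(residual, yhat) {
  residual$sigma_add^2 + (residual$sigma_prop * yhat)^2
}

#' Joint log density log p(y | eta) + log p(eta)
#'
#' Gaussian observation log-likelihood of the residuals (variance
#' `sigma_add^2 + (sigma_prop * yhat)^2` under the combined model) plus
#' the random-effect prior `log N(eta; 0, Omega)`. The per-subject MAP
#' problem maximizes this quantity.
#'
#' @param pop [population_parameters()].
#' @param subject a [subject_record()].
#' @param eta random-effect vector (length `pop$K`).
#' @return scalar log density.
#' @export
log_joint <- function(pop, subject, eta) {
  om <- omega_matrix(pop$omega)
  if (!is_pd(om)) stop("log_joint: Omega (S C S') is not positive definite")
  p <- predict_eta(pop, subject, eta)
  ll <- log_dmvnorm0(eta, om)
  if (length(p$y)) {
    v <- resid_variance(pop$residual, p$y)
    r <- subject$obs_values - p$y
    ll <- ll - 0.5 * sum(log(2 * pi * v) + r^2 / v)
  }
  ll
}

# analytic gradient of log_joint w.r.t. eta
log_joint_grad <- function(pop, subject, eta) {
  om <- omega_matrix(pop$omega)
  p <- predict_eta(pop, subject, eta)
  g <- -solve(om, eta)
  if (length(p$y)) {
    v <- resid_variance(pop$residual, p$y)
    r <- subject$obs_values - p$y
    dl_dy <- r / v + pop$residual$sigma_prop^2 * p$y * (r^2 / v^2 - 1 / v)
    g <- g + drop(crossprod(p$G, dl_dy))
  }
  g
}

#' MAP estimate of a subject's random effects
#'
#' Maximizes the joint likelihood `p(y | eta) p(eta)` over `eta` with a
#' box-constrained BFGS search (L-BFGS-B) started at the prior mode
#' (`eta = 0`) and constrained to `[-3, 3]` per component.
#'
#' @param pop [population_parameters()].
#' @param subject a [subject_record()].
#' @param start optional warm start.
#' @param bound box half-width (3 by default).
#' @return the estimated `eta` vector.
#' @export
map_estimate <- function(pop, subject, start = NULL, bound = 3) {
  K <- pop$K
  if (length(subject$obs_times) == 0L) return(numeric(K))
  st <- if (is.null(start)) numeric(K) else pmin(pmax(start, -bound), bound)
  res <- stats::optim(st,
                      fn = function(e) -log_joint(pop, subject, e),
                      gr = function(e) -log_joint_grad(pop, subject, e),
                      method = "L-BFGS-B", lower = rep(-bound, K),
                      upper = rep(bound, K),
                      control = list(maxit = 100))
  if (res$convergence != 0 && res$convergence != 1) {
    warning("map_estimate: optimizer did not converge (code ", res$convergence,
            "); returning best iterate")
  }
  res$par
}

# per-subject FO/FOCE contribution: log det V + r' V^-1 r  (+ n log 2pi)
marginal_term <- function(y, yhat, G, om, vdiag, eta_shift = NULL, id = "?") {
  r <- y - yhat
  if (!is.null(eta_shift)) r <- r + drop(G %*% eta_shift)
  V <- G %*% om %*% t(G) + diag(vdiag, length(y))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) stop("marginal covariance V not positive definite for subject ", id)
  u <- backsolve(ch, r, transpose = TRUE)
  2 * sum(log(diag(ch))) + sum(u^2) + length(y) * log(2 * pi)
}

#' First-order (FO) objective
#'
#' -2 times the FO approximate marginal log-likelihood: the model is
#' linearized in `eta` at the population mean (zero), giving per-subject
#' Gaussian marginals with covariance `V = G Omega G' + Sigma` where
#' `G = d yhat / d eta` at `eta = 0`.
#'
#' @param pop [population_parameters()].
#' @param subjects list of [subject_record()]s.
#' @return scalar objective (sum over subjects of
#'   `log det V + r' V^-1 r + n_i log 2 pi`).
#' @export
fo_objective <- function(pop, subjects) {
  om <- omega_matrix(pop$omega)
  if (!is_pd(om)) stop("fo_objective: Omega (S C S') is not positive definite")
  tot <- 0
  for (s in subjects) {
    if (length(s$obs_times) == 0L) next
    p <- predict_eta(pop, s, numeric(pop$K))
    v <- resid_variance(pop$residual, p$y)
    tot <- tot + marginal_term(s$obs_values, p$y, p$G, om, v, id = s$id)
  }
  tot
}

#' FOCE objective (extended least squares)
#'
#' First-order conditional estimation: the model is linearized at each
#' subject's MAP estimate `eta_hat`. With the NONMEM-style shifted
#' residual `r = y - yhat(eta_hat) + G eta_hat` and
#' `V = G Omega G' + Sigma`, the objective is
#' `sum_i [log det V_i + r_i' V_i^-1 r_i + n_i log 2 pi]`. Under the
#' default `"interaction"` formulation the residual variance is evaluated
#' at the conditional prediction `yhat(eta_hat)`; `"no_interaction"`
#' evaluates it at the typical prediction.
#'
#' @param pop [population_parameters()].
#' @param subjects list of [subject_record()]s.
#' @param eta_hats matrix (subjects x K) of MAP estimates, e.g. from
#'   [map_estimate()]; defaults to zeros (in which case FOCE equals FO).
#' @param formulation `"interaction"` (default) or `"no_interaction"`.
#' @return scalar objective.
#' @export
foce_objective <- function(pop, subjects, eta_hats = NULL,
                           formulation = c("interaction", "no_interaction")) {
  formulation <- match.arg(formulation)
  om <- omega_matrix(pop$omega)
  if (!is_pd(om)) stop("foce_objective: Omega (S C S') is not positive definite")
  if (is.null(eta_hats)) eta_hats <- matrix(0, length(subjects), pop$K)
  tot <- 0
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (length(s$obs_times) == 0L) next
    eh <- eta_hats[i, ]
    p <- predict_eta(pop, s, eh)
    yv <- if (formulation == "interaction") p$y else predict_eta(pop, s, numeric(pop$K))$y
    v <- resid_variance(pop$residual, yv)
    tot <- tot + marginal_term(s$obs_values, p$y, p$G, om, v, eta_shift = eh, id = s$id)
  }
  tot
}

#' Mean-squared-error objective of typical predictions
#'
#' Plain MSE of the typical (eta = 0) predictions over all observations;
#' no population parameters (Omega, Sigma) are involved.
#'
#' @param pop [population_parameters()].
#' @param subjects list of [subject_record()]s.
#' @return scalar mean squared error ((IU/dL)^2).
#' @export
mse_objective <- function(pop, subjects) {
  num <- 0; den <- 0L
  for (s in subjects) {
    if (length(s$obs_times) == 0L) next
    p <- predict_eta(pop, s, numeric(pop$K))
    num <- num + sum((s$obs_values - p$y)^2)
    den <- den + length(p$y)
  }
  if (den == 0L) stop("mse_objective: no observations")
  num / den
}

## ---------------------------------------------------------------------
## Variational posterior and ELBO
## ---------------------------------------------------------------------

#' Per-subject full-rank Gaussian variational posterior
#'
#' `q(eta) = N(mu, L L')` with `L` lower triangular with positive
#' diagonal.
#'
#' @param mu mean vector.
#' @param L lower-triangular factor.
#' @return a `variational_posterior` object.
#' @export
variational_posterior <- function(mu, L) {
  L <- as.matrix(L)
  stopifnot(length(mu) == nrow(L), nrow(L) == ncol(L))
  if (any(L[upper.tri(L)] != 0) || any(diag(L) <= 0)) {
    stop("variational_posterior: L must be lower triangular with positive diagonal")
  }
  structure(list(mu = as.numeric(mu), L = L), class = "variational_posterior")
}

log_q_gauss <- function(q, eta) {
  u <- forwardsolve(q$L, eta - q$mu)
  -sum(log(diag(q$L))) - 0.5 * sum(u^2) - 0.5 * length(eta) * log(2 * pi)
}

#' Monte-Carlo ELBO estimate for one subject
#'
#' Reparametrized estimate of `E_q[log p(y, eta) - log q(eta)]` using
#' `eta = mu + L eps`, `eps ~ N(0, I)`. The `estimator` choice does not
#' affect the value for fixed draws - only which gradient paths are
#' tracked (see [elbo_grad()]).
#'
#' @param pop [population_parameters()].
#' @param q [variational_posterior()].
#' @param subject a [subject_record()].
#' @param n_mc number of Monte-Carlo samples (>= 1).
#' @param estimator `"path_derivative"` (default) or `"standard"`.
#' @param rng_seed optional seed for the draws.
#' @param eps optional `n_mc x K` matrix of standard-normal draws
#'   (overrides the RNG; used to share draws across estimators).
#' @return scalar stochastic ELBO estimate with the draws attached as
#'   attribute `"eps"`.
#' @export
elbo <- function(pop, q, subject, n_mc = 3,
                 estimator = c("path_derivative", "standard"),
                 rng_seed = NULL, eps = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(n_mc >= 1)
  K <- pop$K
  if (is.null(eps)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    eps <- matrix(stats::rnorm(n_mc * K), n_mc, K)
  }
  vals <- vapply(seq_len(nrow(eps)), function(s) {
    eta <- q$mu + drop(q$L %*% eps[s, ])
    if (any(!is.finite(eta))) stop("elbo: non-finite eta sample")
    log_joint(pop, subject, eta) - log_q_gauss(q, eta)
  }, 0)
  structure(mean(vals), eps = eps)
}

#' ELBO gradient with respect to the variational parameters
#'
#' Reparametrized Monte-Carlo gradient of the per-subject ELBO w.r.t.
#' `mu` and `L`. Under `"path_derivative"` the score term (the direct
#' dependence of `log q` on its own parameters) is dropped; this
#' estimator has zero variance - and is exactly zero - when `q` equals
#' the true posterior. The `"standard"` estimator keeps the score term.
#'
#' @inheritParams elbo
#' @return list with `dmu`, `dL` (lower-triangular gradient) and the
#'   draws `eps`.
#' @export
elbo_grad <- function(pop, q, subject, n_mc = 3,
                      estimator = c("path_derivative", "standard"),
                      rng_seed = NULL, eps = NULL) {
  estimator <- match.arg(estimator)
  K <- pop$K
  if (is.null(eps)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    eps <- matrix(stats::rnorm(n_mc * K), n_mc, K)
  }
  dmu <- numeric(K)
  dL <- matrix(0, K, K)
  for (s in seq_len(nrow(eps))) {
    eta <- q$mu + drop(q$L %*% eps[s, ])
    # d/d eta of [log p(y, eta) - log q(eta)]
    u <- forwardsolve(q$L, eta - q$mu)
    dlogq_deta <- -backsolve(t(q$L), u)
    g <- log_joint_grad(pop, subject, eta) - dlogq_deta
    dmu <- dmu + g
    dL <- dL + tcrossprod(g, eps[s, ])
    if (estimator == "standard") {
      # direct (score) dependence of -log q(eta; phi) on phi, eta held fixed
      dmu <- dmu + dlogq_deta
      Linv_t_u <- backsolve(t(q$L), u)
      dL <- dL + diag(1 / diag(q$L), K) - tcrossprod(Linv_t_u, u)
    }
  }
  dL[upper.tri(dL)] <- 0
  list(dmu = dmu / nrow(eps), dL = dL / nrow(eps), eps = eps)
}
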