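# MCMC reference posteriors for validating variational approximations.
# Scenario 1 fixes the full population parameters at their true values
# and samples each subject's 2-d random-effect posterior independently
# (conditional independence given Theta). Scenario 2 additionally samples
# the decomposed random-effect covariance (marginal SDs S, correlation C)
# and the residual SD, with weakly informative priors: half-Normal(0.5)
# on S, LKJ(2) on C, half-Normal(5 IU/dL) on sigma_add.

#' MCMC configuration
#'
#' @param scenario 1 (population parameters fixed at truth, sample eta
#'   only) or 2 (also sample Omega and the residual SD).
#' @param n_samples posterior draws kept (defaults: 10000 for scenario 1,
#'   5000 for scenario 2).
#' @param n_warmup warmup iterations (discarded).
#' @param seed integer RNG seed.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(scenario = 1, n_samples = if (scenario == 1) 10000 else 5000,
                        n_warmup = 1000, seed = 1L) {
  stopifnot(scenario %in% c(1, 2), n_samples > 0, n_warmup >= 100)
  structure(list(scenario = scenario, n_samples = n_samples,
                 n_warmup = n_warmup, seed = seed),
            class = "mcmc_config")
}

#' Sample the reference posterior with NUTS
#'
#' @param pop_truth [population_parameters()] holding the true typical
#'   model; in scenario 1 its Omega and residual model are the fixed
#'   truth, in scenario 2 they only seed the initialization.
#' @param subjects list of [subject_record()]s.
#' @param cfg an [mcmc_config()].
#' @return a `posterior_samples` object: `eta` is a draws x subjects x 2
#'   array; scenario 2 adds a `globals` data.frame with columns `s1`,
#'   `s2`, `rho`, `sigma_add`.
#' @export
sample_reference <- function(pop_truth, subjects, cfg = mcmc_config()) {
  ws <- make_workspace(subjects)
  zeta <- typical_params(pop_truth$theta, ws$X)
  CL <- rep_len(zeta$CL, ws$n); V1 <- rep_len(zeta$V1, ws$n)
  Q <- zeta$Q[1]; V2 <- zeta$V2[1]
  om <- omega_matrix(pop_truth$omega)
  vr <- list(s1 = pop_truth$omega$S[1], s2 = pop_truth$omega$S[2],
             rho = pop_truth$omega$C[1, 2],
             siga = pop_truth$residual$sigma_add,
             sigp = pop_truth$residual$sigma_prop)
  n <- ws$n
  n_div <- 0L

  if (cfg$scenario == 1) {
    eta <- array(NA_real_, c(cfg$n_samples, n, 2))
    for (i in seq_len(n)) {
      fn <- subject_joint_fn(ws, i, CL[i], V1[i], Q, V2, vr, om)
      res <- nuts_sample(fn, c(0, 0), cfg$n_samples, cfg$n_warmup,
                         seed = child_seed(cfg$seed, i))
      eta[, i, ] <- res$draws
      n_div <- n_div + res$n_divergent
    }
    globals <- NULL
  } else {
    # x = (u_s1, u_s2, u_rho, u_siga, eta_1..eta_n interleaved by subject)
    os <- ws$obs_subj
    logp <- function(x) {
      u <- x[1:4]
      eta1 <- x[4 + seq_len(n)]
      eta2 <- x[4 + n + seq_len(n)]
      lik_prior <- function(uc, e1, e2) {
        s1 <- softplus(uc[1]); s2 <- softplus(uc[2])
        rho <- tanh(uc[3]); siga <- softplus(uc[4])
        p <- fast_pred(ws, CL, V1, Q, V2, e1, e2, grad = FALSE)
        v <- siga^2 + (vr$sigp * p$y)^2
        rres <- ws$obs_y - p$y
        ll <- sum(-0.5 * (log(2 * pi * v) + rres * rres / v))
        lpe <- sum(lp_eta2d(e1, e2, s1 * s1, s1 * s2 * rho, s2 * s2))
        # priors + transform Jacobians (softplus: log sigmoid(u);
        # tanh: log(1 - rho^2)); LKJ(2) density propto (1 - rho^2)
        lpr <- -0.5 * (s1 / 0.5)^2 - 0.5 * (s2 / 0.5)^2 +
          log(1 - rho * rho) - 0.5 * (siga / 5)^2 +
          log(sigmoid(uc[1])) + log(sigmoid(uc[2])) +
          log(1 - rho * rho) + log(sigmoid(uc[4]))
        ll + lpe + lpr
      }
      s1 <- as.numeric(softplus(u[1])); s2 <- as.numeric(softplus(u[2]))
      rho <- as.numeric(tanh(u[3])); siga <- as.numeric(softplus(u[4]))
      p <- fast_pred(ws, CL, V1, Q, V2, eta1, eta2)
      v <- siga^2 + (vr$sigp * p$y)^2
      rres <- ws$obs_y - p$y
      dl_dy <- rres / v + vr$sigp^2 * p$y * (rres^2 / v^2 - 1 / v)
      g1 <- rowsum_c(p$G1 * dl_dy, os, n)
      g2 <- rowsum_c(p$G2 * dl_dy, os, n)
      w11 <- s1^2; w12 <- s1 * s2 * rho; w22 <- s2^2
      det <- w11 * w22 - w12^2
      ge1 <- g1 - (w22 * eta1 - w12 * eta2) / det
      ge2 <- g2 - (-w12 * eta1 + w11 * eta2) / det
      gu <- vapply(1:4, function(j) {
        uc <- as.complex(u); uc[j] <- uc[j] + CSTEP * 1i
        Im(lik_prior(uc, eta1, eta2)) / CSTEP
      }, 0)
      list(value = as.numeric(lik_prior(u, eta1, eta2)),
           grad = c(gu, ge1, ge2))
    }
    init <- c(softplus_inv(pmax(c(vr$s1, vr$s2), 0.05)), atanh(vr$rho * 0.5),
              softplus_inv(max(vr$siga, 0.5)), rep(0, 2 * n))
    res <- nuts_sample(logp, init, cfg$n_samples, cfg$n_warmup, seed = cfg$seed)
    n_div <- res$n_divergent
    eta <- array(NA_real_, c(cfg$n_samples, n, 2))
    eta[, , 1] <- res$draws[, 4 + seq_len(n)]
    eta[, , 2] <- res$draws[, 4 + n + seq_len(n)]
    globals <- data.frame(
      s1 = as.numeric(softplus(res$draws[, 1])),
      s2 = as.numeric(softplus(res$draws[, 2])),
      rho = tanh(res$draws[, 3]),
      sigma_add = as.numeric(softplus(res$draws[, 4]))
    )
  }
  total_trans <- cfg$n_samples + cfg$n_warmup
  frac <- n_div / max(total_trans * if (cfg$scenario == 1) n else 1, 1)
  if (frac > 0.01) {
    warning(sprintf("sample_reference: %.1f%% divergent transitions", 100 * frac))
  }
  structure(list(scenario = cfg$scenario, eta = eta, globals = globals,
                 n_divergent = n_div, config = cfg,
                 subject_ids = vapply(subjects, `[[`, "", "id")),
            class = "posterior_samples")
}

#' 2-Wasserstein distance between two Gaussians
#'
#' Closed form: `W2^2 = |mu1 - mu2|^2 +
#' tr(S1 + S2 - 2 (S2^{1/2} S1 S2^{1/2})^{1/2})`.
#'
#' @param mu1,mu2 mean vectors.
#' @param S1,S2 covariance matrices.
#' @return the distance (a scalar, >= 0).
#' @export
w2_gaussian <- function(mu1, S1, mu2, S2) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  b <- sqrtm_psd(S2)
  cross <- sqrtm_psd(b %*% S1 %*% b)
  d2 <- sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * sum(diag(cross))
  sqrt(max(d2, 0))
}

#' Compare variational and MCMC random-effect posteriors
#'
#' Per-subject 2-Wasserstein distance between the Gaussian `q` and a
#' Gaussian moment-match of the MCMC draws, plus 95% ellipse overlay
#' data for plotting.
#'
#' @param vi_q list of [variational_posterior()]s (one per subject).
#' @param mcmc a `posterior_samples` object over the same subjects.
#' @return list with `by_subject` (data.frame of distances),
#'   `median_w2`, and `ellipses` (long data.frame of 95% contour points
#'   for both posteriors).
#' @export
compare_posteriors <- function(vi_q, mcmc) {
  stopifnot(inherits(mcmc, "posterior_samples"))
  n <- dim(mcmc$eta)[2]
  if (length(vi_q) != n) stop("compare_posteriors: subject mismatch")
  if (dim(mcmc$eta)[1] < 100) {
    stop("compare_posteriors: need at least 100 MCMC draws for stable moments")
  }
  th <- seq(0, 2 * pi, length.out = 73)
  circ <- rbind(cos(th), sin(th)) * sqrt(stats::qchisq(0.95, df = 2))
  rows <- vector("list", n)
  ell <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    dr <- mcmc$eta[, i, ]
    m2 <- colMeans(dr)
    S2 <- stats::cov(dr)
    q <- vi_q[[i]]
    S1 <- tcrossprod(q$L)
    rows[[i]] <- data.frame(subject = i, w2 = w2_gaussian(q$mu, S1, m2, S2))
    ell[[2L * i - 1L]] <- data.frame(subject = i, source = "vi",
                                     eta1 = (sqrtm_psd(S1) %*% circ)[1, ] + q$mu[1],
                                     eta2 = (sqrtm_psd(S1) %*% circ)[2, ] + q$mu[2])
    ell[[2L * i]] <- data.frame(subject = i, source = "mcmc",
                                eta1 = (sqrtm_psd(S2) %*% circ)[1, ] + m2[1],
                                eta2 = (sqrtm_psd(S2) %*% circ)[2, ] + m2[2])
  }
  by_subject <- do.call(rbind, rows)
  list(by_subject = by_subject,
       median_w2 = stats::median(by_subject$w2),
       ellipses = do.call(rbind, ell))
}
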