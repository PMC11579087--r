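# Vectorized objective/gradient engine behind dcm_fit(). Algebraically
# identical to the per-subject reference implementations in objectives.R
# (asserted in the tests), but evaluated over all subjects at once.
#
# Gradient scheme: per-subject structural parameters (CL_i, V1_i) and the
# shared raw parameters are differentiated by complex step through the
# analytic two-compartment solution and its closed-form CL/V1
# sensitivities (everything on that path is complex-analytic); the
# resulting d(loss)/d(pre-activation) terms are then backpropagated
# through the branch networks in closed form. The marginal covariance
# V = G Omega G' + Sigma is handled by the Woodbury identity, so only
# 2x2 determinants/inverses appear and the whole evaluation vectorizes
# over subjects with arbitrary ragged observation counts.

make_workspace <- function(subjects) {
  ws <- flatten_subjects(subjects)
  ws$pair_by_subj <- split(seq_along(ws$pair_obs), ws$pair_subj)
  ws$obs_by_subj <- split(seq_len(ws$m), ws$obs_subj)
  ws
}

# predictions (and d y/d eta) for all observation rows at per-subject eta
fast_pred <- function(ws, CL, V1, Q, V2, eta1 = NULL, eta2 = NULL, grad = TRUE) {
  ps <- ws$pair_subj
  zCL <- if (is.null(eta1)) CL else CL * exp(eta1)
  zV1 <- if (is.null(eta2)) V1 else V1 * exp(eta2)
  r <- pk_conc_pairs(zCL[ps], zV1[ps], rep(Q, length(ps)), rep(V2, length(ps)),
                     ws$pair_dose_t, ws$pair_amt, ws$pair_dur, ws$pair_time,
                     grad = grad)
  if (!grad) return(list(y = rowsum_c(r, ws$pair_obs, ws$m)))
  os <- ws$obs_subj
  list(y = rowsum_c(r$c, ws$pair_obs, ws$m),
       G1 = zCL[os] * rowsum_c(r$dCL, ws$pair_obs, ws$m),
       G2 = zV1[os] * rowsum_c(r$dV1, ws$pair_obs, ws$m))
}

# bivariate normal log density at (eta1, eta2), vectorized, complex-capable
lp_eta2d <- function(eta1, eta2, w11, w12, w22) {
  det <- w11 * w22 - w12 * w12
  q <- (w22 * eta1 * eta1 - 2 * w12 * eta1 * eta2 + w11 * eta2 * eta2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# Per-subject FO/FOCE contributions l_i = log det V_i + r_i' V_i^-1 r_i
# + n_i log 2pi, via Woodbury. Returns a length-n vector (complex when
# any input is perturbed).
fast_marginal_vec <- function(ws, CL, V1, Q, V2, vr, eta_hats = NULL,
                              formulation = "interaction") {
  os <- ws$obs_subj
  if (is.null(eta_hats)) {
    p <- fast_pred(ws, CL, V1, Q, V2)
    yhat <- p$y
    rres <- ws$obs_y - yhat
    yv <- yhat
  } else {
    e1 <- eta_hats[, 1]; e2 <- eta_hats[, 2]
    p <- fast_pred(ws, CL, V1, Q, V2, e1, e2)
    yhat <- p$y
    rres <- ws$obs_y - yhat + p$G1 * e1[os] + p$G2 * e2[os]
    yv <- if (formulation == "interaction") yhat
          else fast_pred(ws, CL, V1, Q, V2, grad = FALSE)$y
  }
  v <- vr$siga^2 + (vr$sigp * yv)^2
  G1 <- p$G1; G2 <- p$G2
  n <- ws$n
  slog <- rowsum_c(log(v), os, n)
  a11 <- rowsum_c(G1 * G1 / v, os, n)
  a12 <- rowsum_c(G1 * G2 / v, os, n)
  a22 <- rowsum_c(G2 * G2 / v, os, n)
  b1 <- rowsum_c(G1 * rres / v, os, n)
  b2 <- rowsum_c(G2 * rres / v, os, n)
  rr <- rowsum_c(rres * rres / v, os, n)

  w11 <- vr$s1 * vr$s1
  w12 <- vr$s1 * vr$s2 * vr$rho
  w22 <- vr$s2 * vr$s2
  # N = I + A Omega (2x2 per subject)
  n11 <- 1 + a11 * w11 + a12 * w12
  n12 <- a11 * w12 + a12 * w22
  n21 <- a12 * w11 + a22 * w12
  n22 <- 1 + a12 * w12 + a22 * w22
  detN <- n11 * n22 - n12 * n21
  # correction b' Omega (I + A Omega)^-1 b  (= b' (Omega^-1 + A)^-1 b;
  # note Omega N^-1 is symmetric while N^-1 Omega is not)
  u1 <- (n22 * b1 - n12 * b2) / detN
  u2 <- (-n21 * b1 + n11 * b2) / detN
  corr <- b1 * (w11 * u1 + w12 * u2) + b2 * (w12 * u1 + w22 * u2)
  slog + log(detN) + rr - corr + ws$nobs * log(2 * pi)
}

# mean-squared-error contributions: per-subject SSE (complex-capable)
fast_sse_vec <- function(ws, CL, V1, Q, V2) {
  p <- fast_pred(ws, CL, V1, Q, V2, grad = FALSE)
  rres <- ws$obs_y - p$y
  rowsum_c(rres * rres, ws$obs_subj, ws$n)
}

# forward pass + shared complex-step/backprop bookkeeping ---------------

# evaluate per-subject objective vector under a one-direction perturbation
# `which` of the structural/raw parameters; `evalfun(CL, V1, Q, V2, vr)`.
cs_directions <- function(evalfun, fwd, vr, raw, lay, h = CSTEP) {
  n <- length(fwd$CL)
  # structural directions (per-subject, simultaneous since l_i depends
  # only on subject i's own parameters)
  dCL <- Im(evalfun(fwd$CL + h * 1i, fwd$V1, fwd$Q, fwd$V2, vr)) / h
  dV1 <- Im(evalfun(fwd$CL, fwd$V1 + h * 1i, fwd$Q, fwd$V2, vr)) / h
  dQraw <- sum(Im(evalfun(fwd$CL, fwd$V1, softplus(fwd$Qraw + h * 1i), fwd$V2, vr))) / h
  dV2raw <- sum(Im(evalfun(fwd$CL, fwd$V1, fwd$Q, softplus(fwd$V2raw + h * 1i), vr))) / h
  # shared raw variance-like directions
  nvar <- lay$K + lay$nrho + lay$nsig
  dvar <- numeric(nvar)
  for (j in seq_len(nvar)) {
    rawc <- as.complex(raw)
    rawc[lay$nnet + j] <- rawc[lay$nnet + j] + h * 1i
    vrc <- var_from_raw(rawc, lay)
    dvar[j] <- sum(Im(evalfun(fwd$CL, fwd$V1, fwd$Q, fwd$V2, vrc))) / h
  }
  list(dCL = dCL, dV1 = dV1, dQraw = dQraw, dV2raw = dV2raw, dvar = dvar)
}

net_forward_raw <- function(raw, skel, ws, lay) {
  theta <- net_unpack(raw[seq_len(lay$nnet)], skel$theta)
  f <- net_forward(theta, ws$X, cache = TRUE)
  list(theta = theta, cache = f,
       CL = f$CL, V1 = f$V1, Q = f$Q, V2 = f$V2,
       Qraw = theta$globals[["Q"]], V2raw = theta$globals[["V2"]],
       pre_CL = f$pre_CL, pre_V1 = f$pre_V1)
}

assemble_grad <- function(fwd, d, lay) {
  dpre_CL <- d$dCL * as.numeric(sigmoid(fwd$pre_CL))
  dpre_V1 <- d$dV1 * as.numeric(sigmoid(fwd$pre_V1))
  gnet <- net_backprop(fwd$theta, fwd$cache, dpre_CL, dpre_V1, d$dQraw, d$dV2raw)
  c(gnet, d$dvar)
}

# FO / FOCE / MSE value+gradient in the raw parametrization -------------

fast_obj_grad <- function(raw, skel, ws, objective,
                          eta_hats = NULL, formulation = "interaction") {
  lay <- raw_layout(skel)
  fwd <- net_forward_raw(raw, skel, ws, lay)
  vr <- var_from_raw(raw, lay)
  if (!is.null(vr$rho) && (vr$s1 <= 0 || vr$s2 <= 0 || abs(vr$rho) >= 1)) {
    stop("fast_obj_grad: Omega is not positive definite")
  }
  evalfun <- switch(objective,
    mse = function(CL, V1, Q, V2, vr) fast_sse_vec(ws, CL, V1, Q, V2),
    fo = function(CL, V1, Q, V2, vr)
      fast_marginal_vec(ws, CL, V1, Q, V2, vr),
    foce = function(CL, V1, Q, V2, vr)
      fast_marginal_vec(ws, CL, V1, Q, V2, vr, eta_hats, formulation),
    stop("unknown objective ", objective))
  val_vec <- evalfun(fwd$CL, fwd$V1, fwd$Q, fwd$V2, vr)
  d <- cs_directions(evalfun, fwd, vr, raw, lay)
  g <- assemble_grad(fwd, d, lay)
  value <- sum(val_vec)
  if (objective == "mse") {
    value <- value / ws$m
    g <- g / ws$m
  } else {
    # variance-like raw entries do not exist in the MSE gradient but are
    # carried as zeros for a uniform parameter vector
  }
  list(value = value, grad = g)
}

# Per-subject joint log density log p(y_i | eta) + log N(eta; 0, Omega)
# with its analytic eta-gradient, as a closure over the flattened data.
# Shared by the FOCE MAP refresh and the scenario-1 NUTS sampler.
subject_joint_fn <- function(ws, i, CL, V1, Q, V2, vr, om) {
  om_inv <- solve(om)
  logdet_om <- determinant(om)$modulus[1]
  pi_ <- ws$pair_by_subj[[as.character(i)]]
  oi <- ws$obs_by_subj[[as.character(i)]]
  if (is.null(oi) || length(oi) == 0L || is.null(pi_)) {
    return(function(e) list(value = -log(2 * pi) - 0.5 * logdet_om -
                              0.5 * drop(e %*% om_inv %*% e),
                            grad = -drop(om_inv %*% e)))
  }
  yobs <- ws$obs_y[oi]
  rel_obs <- match(ws$pair_obs[pi_], oi)
  nobs <- length(oi)
  np <- length(pi_)
  dt <- ws$pair_dose_t[pi_]; am <- ws$pair_amt[pi_]
  du <- ws$pair_dur[pi_]; tm <- ws$pair_time[pi_]
  function(e) {
    zCL <- CL * exp(e[1]); zV1 <- V1 * exp(e[2])
    r <- pk_conc_pairs(rep(zCL, np), rep(zV1, np), rep(Q, np), rep(V2, np),
                       dt, am, du, tm, grad = TRUE)
    yhat <- rowsum_c(r$c, rel_obs, nobs)
    G1 <- zCL * rowsum_c(r$dCL, rel_obs, nobs)
    G2 <- zV1 * rowsum_c(r$dV1, rel_obs, nobs)
    v <- vr$siga^2 + (vr$sigp * yhat)^2
    res <- yobs - yhat
    lp <- -0.5 * sum(log(2 * pi * v) + res^2 / v) -
      log(2 * pi) - 0.5 * logdet_om - 0.5 * drop(e %*% om_inv %*% e)
    dl_dy <- res / v + vr$sigp^2 * yhat * (res^2 / v^2 - 1 / v)
    gr <- c(sum(G1 * dl_dy), sum(G2 * dl_dy)) - drop(om_inv %*% e)
    list(value = lp, grad = gr)
  }
}

# per-subject MAP refresh for FOCE (box-constrained BFGS, warm-started)
fast_map_all <- function(ws, CL, V1, Q, V2, vr, start = NULL, bound = 3) {
  n <- ws$n
  om <- matrix(c(vr$s1^2, vr$s1 * vr$s2 * vr$rho,
                 vr$s1 * vr$s2 * vr$rho, vr$s2^2), 2, 2)
  if (!is_pd(om)) stop("fast_map_all: Omega is not positive definite")
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    oi <- ws$obs_by_subj[[as.character(i)]]
    if (is.null(oi) || length(oi) == 0L) next
    fn <- subject_joint_fn(ws, i, CL[i], V1[i], Q, V2, vr, om)
    st <- if (is.null(start)) c(0, 0) else pmin(pmax(start[i, ], -bound), bound)
    res <- stats::optim(st, fn = function(e) -fn(e)$value,
                        gr = function(e) -fn(e)$grad,
                        method = "L-BFGS-B",
                        lower = c(-bound, -bound), upper = c(bound, bound),
                        control = list(maxit = 50))
    out[i, ] <- res$par
  }
  out
}

# VI: joint value+gradient over (population raw | per-subject phi) ------
# phi layout per subject: mu1, mu2, l11raw, l21, l22raw (diagonals of L
# through softplus).

vi_phi_init <- function(n, L0 = 0.1) {
  matrix(rep(c(0, 0, softplus_inv(L0), 0, softplus_inv(L0)), each = n), n, 5)
}

fast_vi_grad <- function(raw, phi, skel, ws, n_mc = 3,
                         estimator = "path_derivative", eps = NULL) {
  lay <- raw_layout(skel)
  fwd <- net_forward_raw(raw, skel, ws, lay)
  vr <- var_from_raw(raw, lay)
  n <- ws$n
  os <- ws$obs_subj
  if (is.null(eps)) eps <- array(stats::rnorm(n * 2 * n_mc), c(n, 2, n_mc))
  n_mc <- dim(eps)[3]
  mu1 <- phi[, 1]; mu2 <- phi[, 2]
  l11 <- as.numeric(softplus(phi[, 3])); l21 <- phi[, 4]
  l22 <- as.numeric(softplus(phi[, 5]))
  w11 <- vr$s1^2; w12 <- vr$s1 * vr$s2 * vr$rho; w22 <- vr$s2^2
  detom <- w11 * w22 - w12^2
  oi11 <- w22 / detom; oi12 <- -w12 / detom; oi22 <- w11 / detom

  val <- numeric(n)
  dmu1 <- dmu2 <- dl11 <- dl21 <- dl22 <- numeric(n)
  eta_store <- vector("list", n_mc)

  # observation log-likelihood per subject for fixed eta draws; complex-
  # capable in the structural parameters and residual SDs
  ll_eval <- function(CL, V1, Q, V2, vrx) {
    tot <- 0
    for (s in seq_len(n_mc)) {
      es <- eta_store[[s]]
      p <- fast_pred(ws, CL, V1, Q, V2, es$eta1, es$eta2, grad = FALSE)
      v <- vrx$siga^2 + (vrx$sigp * p$y)^2
      rres <- ws$obs_y - p$y
      tot <- tot + rowsum_c(-0.5 * (log(2 * pi * v) + rres * rres / v), os, n)
    }
    tot / n_mc
  }
  lp_eval <- function(vrx) {
    tot <- 0
    for (s in seq_len(n_mc)) {
      es <- eta_store[[s]]
      tot <- tot + lp_eta2d(es$eta1, es$eta2, vrx$s1^2,
                            vrx$s1 * vrx$s2 * vrx$rho, vrx$s2^2)
    }
    tot / n_mc
  }

  for (s in seq_len(n_mc)) {
    e1 <- eps[, 1, s]; e2 <- eps[, 2, s]
    eta1 <- mu1 + l11 * e1
    eta2 <- mu2 + l21 * e1 + l22 * e2
    eta_store[[s]] <- list(eta1 = eta1, eta2 = eta2)
    p <- fast_pred(ws, fwd$CL, fwd$V1, fwd$Q, fwd$V2, eta1, eta2)
    v <- vr$siga^2 + (vr$sigp * p$y)^2
    rres <- ws$obs_y - p$y
    ll <- rowsum_c(-0.5 * (log(2 * pi * v) + rres^2 / v), os, n)
    dl_dy <- rres / v + vr$sigp^2 * p$y * (rres^2 / v^2 - 1 / v)
    g1 <- rowsum_c(p$G1 * dl_dy, os, n)
    g2 <- rowsum_c(p$G2 * dl_dy, os, n)
    lp <- lp_eta2d(eta1, eta2, w11, w12, w22)
    gp1 <- -(oi11 * eta1 + oi12 * eta2)
    gp2 <- -(oi12 * eta1 + oi22 * eta2)
    lq <- -log(l11) - log(l22) - 0.5 * (e1^2 + e2^2) - log(2 * pi)
    # d log q / d eta = -L^-T eps
    x2 <- e2 / l22
    x1 <- (e1 - l21 * x2) / l11
    gq1 <- x1  # minus d log q / d eta_1
    gq2 <- x2
    gt1 <- g1 + gp1 + gq1
    gt2 <- g2 + gp2 + gq2
    val <- val + (ll + lp - lq)
    dmu1 <- dmu1 + gt1
    dmu2 <- dmu2 + gt2
    dl11 <- dl11 + gt1 * e1
    dl21 <- dl21 + gt2 * e1
    dl22 <- dl22 + gt2 * e2
    if (estimator == "standard") {
      dmu1 <- dmu1 - x1
      dmu2 <- dmu2 - x2
      dl11 <- dl11 + (1 / l11 - x1 * e1)
      dl21 <- dl21 - x2 * e1
      dl22 <- dl22 + (1 / l22 - x2 * e2)
    }
  }
  val <- val / n_mc
  dphi <- cbind(dmu1, dmu2,
                dl11 * as.numeric(sigmoid(phi[, 3])),
                dl21,
                dl22 * as.numeric(sigmoid(phi[, 5]))) / n_mc

  # population-parameter gradients (eta draws held fixed)
  h <- CSTEP
  dCL <- Im(ll_eval(fwd$CL + h * 1i, fwd$V1, fwd$Q, fwd$V2, vr)) / h
  dV1 <- Im(ll_eval(fwd$CL, fwd$V1 + h * 1i, fwd$Q, fwd$V2, vr)) / h
  dQraw <- sum(Im(ll_eval(fwd$CL, fwd$V1, softplus(fwd$Qraw + h * 1i), fwd$V2, vr))) / h
  dV2raw <- sum(Im(ll_eval(fwd$CL, fwd$V1, fwd$Q, softplus(fwd$V2raw + h * 1i), vr))) / h
  nvar <- lay$K + lay$nrho + lay$nsig
  dvar <- numeric(nvar)
  for (j in seq_len(nvar)) {
    rawc <- as.complex(raw)
    rawc[lay$nnet + j] <- rawc[lay$nnet + j] + h * 1i
    vrc <- var_from_raw(rawc, lay)
    dvar[j] <- sum(Im(lp_eval(vrc) + ll_eval(fwd$CL, fwd$V1, fwd$Q, fwd$V2, vrc))) / h
  }
  d <- list(dCL = dCL, dV1 = dV1, dQraw = dQraw, dV2raw = dV2raw, dvar = dvar)
  gpop <- assemble_grad(fwd, d, lay)

  # ELBO is maximized: return the negative as the loss to minimize
  list(value = -sum(val), grad_pop = -gpop, grad_phi = -dphi, eps = eps)
}
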