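# Training loop (full-batch ADAM with checkpointing) and the
# fold x replicate experiment grid.

adam_state <- function(p) list(m = numeric(p), v = numeric(p), t = 0L)

adam_update <- function(st, par, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Training configuration
#'
#' @param objective one of `"mse"`, `"fo"`, `"foce"`, `"vi"`.
#' @param learning_rate ADAM learning rate; defaults to 0.1 (0.01 for
#'   FOCE, which needs the lower rate for stability).
#' @param epochs number of full-batch epochs (simulation-study default
#'   2000).
#' @param checkpoint_every checkpoint cadence in epochs.
#' @param trailing_window epochs included in the final parameter mean.
#' @param seed integer seed controlling initialization and all Monte
#'   Carlo draws of the run.
#' @param n_mc Monte-Carlo samples for the ELBO (VI only).
#' @param estimator ELBO gradient estimator (VI only):
#'   `"path_derivative"` (default) or `"standard"`.
#' @param formulation FOCE residual-variance formulation:
#'   `"interaction"` (default) or `"no_interaction"`.
#' @param residual_kind `"additive"` or `"combined"` error model.
#' @param init_omega_sd,init_sigma_add,init_sigma_prop starting values of
#'   the variance components.
#' @return a `training_config` list.
#' @export
training_config <- function(objective = c("vi", "fo", "foce", "mse"),
                            learning_rate = NULL, epochs = 2000,
                            checkpoint_every = 25, trailing_window = 500,
                            seed = 1L, n_mc = 3,
                            estimator = c("path_derivative", "standard"),
                            formulation = c("interaction", "no_interaction"),
                            residual_kind = c("additive", "combined"),
                            init_omega_sd = 0.3, init_sigma_add = 2.5,
                            init_sigma_prop = 0.1, init_q_sd = 0.1) {
  objective <- match.arg(objective)
  if (is.null(learning_rate)) learning_rate <- if (objective == "foce") 0.01 else 0.1
  stopifnot(learning_rate > 0, epochs >= 0,
            epochs == 0 || epochs >= checkpoint_every || checkpoint_every >= 1)
  structure(list(objective = objective, learning_rate = learning_rate,
                 epochs = epochs, checkpoint_every = checkpoint_every,
                 trailing_window = trailing_window, seed = seed, n_mc = n_mc,
                 estimator = match.arg(estimator),
                 formulation = match.arg(formulation),
                 residual_kind = match.arg(residual_kind),
                 init_omega_sd = init_omega_sd,
                 init_sigma_add = init_sigma_add,
                 init_sigma_prop = init_sigma_prop,
                 init_q_sd = init_q_sd),
            class = "training_config")
}

init_skeleton <- function(config, model_spec) {
  theta <- init_network(model_spec, seed = config$seed)
  resid <- if (config$residual_kind == "combined") {
    residual_model("combined", config$init_sigma_add, config$init_sigma_prop)
  } else {
    residual_model("additive", config$init_sigma_add)
  }
  population_parameters(theta,
                        omega_decomposition(rep(config$init_omega_sd, 2)),
                        resid)
}

#' Fit a deep compartment model
#'
#' Full-batch ADAM on the selected objective. For FOCE the per-subject
#' MAP estimates are refreshed at the start of each epoch (warm-started
#' from the previous epoch); for VI the variational parameters are
#' optimized jointly with the population parameters. Checkpoints of the
#' unconstrained parameter vector are saved every `checkpoint_every`
#' epochs and the final parameters are the mean over the trailing
#' window. A run that produces a non-finite loss is marked
#' `status = "failed"` with its partial checkpoints retained.
#'
#' @param config a [training_config()].
#' @param subjects list of [subject_record()]s (the training fold).
#' @param model_spec a [dcm_network_spec()].
#' @param skeleton optional pre-built [population_parameters()] skeleton;
#'   a skeleton with a toy `predfun` switches to the per-subject
#'   reference engine (VI objective only).
#' @return a `dcm_fit` object.
#' @export
dcm_fit <- function(config, subjects, model_spec = dcm_network_spec(),
                    skeleton = NULL) {
  stopifnot(length(subjects) >= 1)
  if (!is.null(skeleton) && !is.null(skeleton$predfun)) {
    return(fit_toy(config, subjects, skeleton))
  }
  skel <- if (is.null(skeleton)) init_skeleton(config, model_spec) else skeleton
  ws <- make_workspace(subjects)
  set.seed(child_seed(config$seed, 17))
  raw <- pop_to_raw(skel)
  lay <- raw_layout(skel)
  is_vi <- config$objective == "vi"
  phi <- if (is_vi) vi_phi_init(ws$n, config$init_q_sd) else NULL
  npar <- lay$total + if (is_vi) length(phi) else 0L
  ad <- adam_state(npar)
  eta_hats <- matrix(0, ws$n, 2)

  ck <- list(); ck_ep <- integer(); ck_val <- numeric()
  status <- "converged"; reason <- NULL
  epoch <- 0L
  while (epoch < config$epochs) {
    epoch <- epoch + 1L
    res <- tryCatch({
      if (config$objective == "foce") {
        fwd <- net_forward_raw(raw, skel, ws, lay)
        vr <- var_from_raw(raw, lay)
        eta_hats <- fast_map_all(ws, fwd$CL, fwd$V1, fwd$Q, fwd$V2, vr,
                                 start = eta_hats)
        fast_obj_grad(raw, skel, ws, "foce", eta_hats, config$formulation)
      } else if (is_vi) {
        r <- fast_vi_grad(raw, phi, skel, ws, n_mc = config$n_mc,
                          estimator = config$estimator)
        list(value = r$value, grad = c(r$grad_pop, as.numeric(r$grad_phi)))
      } else {
        fast_obj_grad(raw, skel, ws, config$objective)
      }
    }, error = function(e) e)
    if (inherits(res, "error") || !is.finite(res$value) || any(!is.finite(res$grad))) {
      status <- "failed"
      reason <- if (inherits(res, "error")) conditionMessage(res) else "non-finite loss"
      break
    }
    par <- c(raw, if (is_vi) as.numeric(phi))
    up <- adam_update(ad, par, res$grad, config$learning_rate)
    ad <- up$state
    raw <- up$par[seq_len(lay$total)]
    if (is_vi) phi <- matrix(up$par[-seq_len(lay$total)], ws$n, 5)
    if (epoch %% config$checkpoint_every == 0L) {
      ck[[length(ck) + 1L]] <- c(raw, if (is_vi) as.numeric(phi))
      ck_ep <- c(ck_ep, epoch)
      ck_val <- c(ck_val, res$value)
    }
  }

  ckm <- if (length(ck)) do.call(rbind, ck) else matrix(numeric(), 0, npar)
  fit <- structure(list(objective = config$objective, config = config,
                        skeleton = skel, n_subjects = length(subjects),
                        checkpoints = ckm, checkpoint_epochs = ck_ep,
                        checkpoint_values = ck_val,
                        status = status, reason = reason,
                        raw_last = raw, phi_last = phi,
                        eta_hats = if (config$objective == "foce") eta_hats),
                   class = "dcm_fit")
  # a diverged run can leave the unconstrained parameters at values whose
  # transform is degenerate (e.g. |rho| = 1); keep the fit object usable
  fit$final_pop <- tryCatch(final_parameters(fit), error = function(e) NULL)
  if (is_vi) fit$final_q <- tryCatch(final_posteriors(fit), error = function(e) NULL)
  if (is.null(fit$final_pop) && fit$status == "converged") {
    fit$status <- "failed"
    fit$reason <- "degenerate final parameters"
  }
  fit
}

# trailing-window mean of the unconstrained checkpoints -> population
final_parameters <- function(fit) {
  lay <- raw_layout(fit$skeleton)
  if (nrow(fit$checkpoints) == 0L) {
    return(pop_from_raw(fit$raw_last, fit$skeleton))
  }
  inwin <- fit$checkpoint_epochs > max(fit$checkpoint_epochs) - fit$config$trailing_window
  wmean <- colMeans(fit$checkpoints[inwin, seq_len(lay$total), drop = FALSE])
  pop_from_raw(wmean, fit$skeleton)
}

# window-averaged variational posteriors (VI fits)
final_posteriors <- function(fit) {
  lay <- raw_layout(fit$skeleton)
  n <- fit$n_subjects
  phim <- if (nrow(fit$checkpoints) > 0L) {
    inwin <- fit$checkpoint_epochs > max(fit$checkpoint_epochs) - fit$config$trailing_window
    matrix(colMeans(fit$checkpoints[inwin, -seq_len(lay$total), drop = FALSE]), n, 5)
  } else {
    fit$phi_last
  }
  lapply(seq_len(n), function(i) {
    L <- matrix(c(softplus(phim[i, 3]), phim[i, 4], 0, softplus(phim[i, 5])), 2, 2)
    variational_posterior(phim[i, 1:2], L)
  })
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("<dcm_fit>", x$objective, "|", x$n_subjects, "subjects |",
      length(x$checkpoint_epochs), "checkpoints | status:", x$status, "\n")
  invisible(x)
}

# Reference-engine trainer for toy models (predfun-based; VI objective,
# scalar random effect, additive error). The two unconstrained population
# parameters (prior SD, residual SD) have closed-form reparametrized
# gradients given the draws; the variational parameters use the analytic
# estimator from elbo_grad().
fit_toy <- function(config, subjects, skeleton) {
  if (config$objective != "vi") {
    stop("fit_toy: only the vi objective is supported for toy skeletons")
  }
  K <- skeleton$K
  if (K != 1L || skeleton$residual$kind != "additive") {
    stop("fit_toy: toy engine supports a scalar random effect with additive error")
  }
  n <- length(subjects)
  lay <- raw_layout(skeleton)
  raw <- pop_to_raw(skeleton)
  qs <- lapply(seq_len(n), function(i)
    variational_posterior(numeric(K), diag(config$init_q_sd, K)))
  nphi <- K + K * (K + 1) / 2
  ad <- adam_state(lay$total + n * nphi)
  set.seed(child_seed(config$seed, 23))
  ck <- list(); ck_ep <- integer(); ck_val <- numeric()
  for (epoch in seq_len(config$epochs)) {
    pop <- pop_from_raw(raw, skeleton)
    omega_sd <- pop$omega$S[1]
    sigma <- pop$residual$sigma_add
    eps_list <- lapply(seq_len(n), function(i)
      matrix(stats::rnorm(config$n_mc * K), config$n_mc, K))
    gphi <- matrix(0, n, nphi)
    d_omega <- 0; d_sigma <- 0
    val <- 0
    for (i in seq_len(n)) {
      g <- elbo_grad(pop, qs[[i]], subjects[[i]], estimator = config$estimator,
                     eps = eps_list[[i]])
      val <- val + as.numeric(elbo(pop, qs[[i]], subjects[[i]], eps = eps_list[[i]]))
      dl <- g$dL[lower.tri(g$dL, diag = TRUE)]
      ddiag <- diag(g$dL) * sigmoid(softplus_inv(diag(qs[[i]]$L)))
      dl[cumsum(seq_len(K))] <- ddiag  # chain softplus on the diagonal
      gphi[i, ] <- c(g$dmu, dl)
      # closed-form gradients of the ELBO w.r.t. the prior and residual
      # SDs for the same draws: d/d_omega log N(eta; 0, omega^2) and
      # d/d_sigma sum_t log N(y_t; yhat_t, sigma^2)
      for (s in seq_len(config$n_mc)) {
        eta <- qs[[i]]$mu + drop(qs[[i]]$L %*% eps_list[[i]][s, ])
        d_omega <- d_omega + (-1 / omega_sd + eta[1]^2 / omega_sd^3) / config$n_mc
        p <- predict_eta(pop, subjects[[i]], eta)
        r <- subjects[[i]]$obs_values - p$y
        d_sigma <- d_sigma +
          sum(-1 / sigma + r^2 / sigma^3) / config$n_mc
      }
    }
    # with a single observation per subject omega^2 and sigma^2 are only
    # jointly identified; a toy skeleton can declare sigma known via
    # fix_residual = TRUE to pin it at its true value
    if (isTRUE(skeleton$fix_residual)) d_sigma <- 0
    graw <- c(d_omega * as.numeric(sigmoid(raw[1])),
              d_sigma * as.numeric(sigmoid(raw[2])))
    par <- c(raw, as.numeric(t(gphi_pack(qs))))
    grad <- -c(graw, as.numeric(t(gphi)))
    up <- adam_update(ad, par, grad, config$learning_rate)
    ad <- up$state
    raw <- up$par[seq_len(lay$total)]
    qs <- gphi_unpack(matrix(up$par[-seq_len(lay$total)], n, nphi, byrow = TRUE), K)
    if (epoch %% config$checkpoint_every == 0L) {
      ck[[length(ck) + 1L]] <- raw; ck_ep <- c(ck_ep, epoch); ck_val <- c(ck_val, -val)
    }
  }
  ckm <- if (length(ck)) do.call(rbind, ck) else matrix(numeric(), 0, lay$total)
  fit <- structure(list(objective = "vi", config = config, skeleton = skeleton,
                        n_subjects = n, checkpoints = ckm,
                        checkpoint_epochs = ck_ep, checkpoint_values = ck_val,
                        status = "converged", reason = NULL,
                        raw_last = raw, final_q = qs),
                   class = "dcm_fit")
  fit$final_pop <- final_parameters(fit)
  fit
}

gphi_pack <- function(qs) {
  t(vapply(qs, function(q) {
    K <- length(q$mu)
    l <- q$L[lower.tri(q$L, diag = TRUE)]
    l[cumsum(seq_len(K))] <- softplus_inv(diag(q$L))
    c(q$mu, l)
  }, numeric(length(qs[[1]]$mu) * (length(qs[[1]]$mu) + 3) / 2)))
}

gphi_unpack <- function(mat, K) {
  lapply(seq_len(nrow(mat)), function(i) {
    mu <- mat[i, seq_len(K)]
    lv <- mat[i, -seq_len(K)]
    L <- matrix(0, K, K)
    L[lower.tri(L, diag = TRUE)] <- lv
    diag(L) <- as.numeric(softplus(diag(L)))
    variational_posterior(mu, L)
  })
}

#' Run the fold x replicate experiment grid
#'
#' Fits every requested objective on every training fold and replicate,
#' evaluates the held-out metrics, and aggregates replicates into
#' Table-style rows (median and SD, with failure counts). One failed
#' replicate never aborts the grid.
#'
#' @param population a simulated `dcm_population` (with design attached).
#' @param plan a [fold_plan()].
#' @param configs named list of [training_config()]s (names are the row
#'   labels, typically the objectives).
#' @param model_spec network architecture for all fits.
#' @param seed master seed; all per-(objective, fold, replicate) child
#'   seeds derive from it and are logged in the run table.
#' @return a `dcm_experiment` list with `runs` (one row per fit) and
#'   `summary` (one row per objective x metric aggregate).
#' @export
run_experiment <- function(population, plan = fold_plan(),
                           configs = list(vi = training_config("vi")),
                           model_spec = dcm_network_spec(), seed = 1L) {
  design <- attr(population, "design")
  omega_true <- if (!is.null(design)) omega_matrix(design$omega) else NULL
  sigma_true <- if (!is.null(design)) design$residual$sigma_add else NULL
  folds <- make_folds(population, plan, seed = seed)
  runs <- list()
  for (obj in names(configs)) {
    cfg0 <- configs[[obj]]
    for (f in seq_along(folds)) {
      for (r in seq_len(plan$replicates_per_fold)) {
        cs <- child_seed(seed, match(obj, names(configs)), f, r)
        cfg <- cfg0; cfg$seed <- cs
        train <- population[folds[[f]]$train_idx]
        test <- population[folds[[f]]$test_idx]
        row <- data.frame(objective = obj, fold = f, replicate = r, seed = cs,
                          status = "failed", rmse = NA_real_,
                          kl_omega = NA_real_, mae_omega1 = NA_real_,
                          mae_omega2 = NA_real_, mae_sigma = NA_real_,
                          stringsAsFactors = FALSE)
        fit <- tryCatch(dcm_fit(cfg, train, model_spec), error = function(e) e)
        if (!inherits(fit, "error")) {
          row$status <- fit$status
          pop_hat <- fit$final_pop
          if (is.null(pop_hat)) row$status <- "failed"
        }
        if (!inherits(fit, "error") && !is.null(fit$final_pop)) {
          pop_hat <- fit$final_pop
          row$rmse <- tryCatch(rmse_typical(pop_hat, test), error = function(e) NA_real_)
          if (obj != "mse" && !is.null(omega_true)) {
            om_hat <- omega_matrix(pop_hat$omega)
            row$kl_omega <- tryCatch(kl_omega(om_hat, omega_true),
                                     error = function(e) NA_real_)
            row$mae_omega1 <- abs(pop_hat$omega$S[1] - sqrt(omega_true[1, 1]))
            row$mae_omega2 <- abs(pop_hat$omega$S[2] - sqrt(omega_true[2, 2]))
            if (!is.null(sigma_true)) {
              row$mae_sigma <- abs(pop_hat$residual$sigma_add - sigma_true)
            }
          }
          if (fit$status == "failed") {
            row[c("rmse", "kl_omega", "mae_omega1", "mae_omega2", "mae_sigma")] <- NA_real_
          }
        }
        runs[[length(runs) + 1L]] <- row
      }
    }
  }
  runs <- do.call(rbind, runs)
  metrics <- c("rmse", "kl_omega", "mae_omega1", "mae_omega2", "mae_sigma")
  summ <- do.call(rbind, lapply(unique(runs$objective), function(obj) {
    sub <- runs[runs$objective == obj, ]
    do.call(rbind, lapply(metrics, function(m) {
      if (obj == "mse" && m != "rmse") return(NULL)
      a <- aggregate_replicates(sub[[m]])
      data.frame(objective = obj, metric = m, median = a$median, sd = a$sd,
                 n = a$n, n_failed = a$n_failed, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(runs = runs, summary = summ, seed = seed, plan = plan),
            class = "dcm_experiment")
}

#' @export
print.dcm_experiment <- function(x, ...) {
  cat("<dcm_experiment>", nrow(x$runs), "fits\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit variational posteriors under a fixed population model
#'
#' Scenario-1 analogue of the MCMC reference: the population parameters
#' (typical model, Omega, residual) are held at the supplied truth and
#' only the per-subject full-rank Gaussian posteriors are optimized, by
#' ADAM on the reparametrized ELBO.
#'
#' @param pop_truth [population_parameters()] with the fixed truth.
#' @param subjects list of [subject_record()]s.
#' @param epochs ADAM epochs.
#' @param learning_rate ADAM learning rate (0.1 as in the study).
#' @param n_mc Monte-Carlo samples per subject per epoch.
#' @param estimator `"path_derivative"` or `"standard"`.
#' @param seed integer RNG seed.
#' @return list of [variational_posterior()]s, one per subject.
#' @export
fit_vi_posteriors <- function(pop_truth, subjects, epochs = 500,
                              learning_rate = 0.1, n_mc = 3,
                              estimator = c("path_derivative", "standard"),
                              seed = 1L) {
  estimator <- match.arg(estimator)
  ws <- make_workspace(subjects)
  zeta <- typical_params(pop_truth$theta, ws$X)
  CL <- rep_len(zeta$CL, ws$n); V1 <- rep_len(zeta$V1, ws$n)
  Q <- zeta$Q[1]; V2 <- zeta$V2[1]
  vr <- list(s1 = pop_truth$omega$S[1], s2 = pop_truth$omega$S[2],
             rho = pop_truth$omega$C[1, 2],
             siga = pop_truth$residual$sigma_add,
             sigp = pop_truth$residual$sigma_prop)
  w11 <- vr$s1^2; w12 <- vr$s1 * vr$s2 * vr$rho; w22 <- vr$s2^2
  detom <- w11 * w22 - w12^2
  oi11 <- w22 / detom; oi12 <- -w12 / detom; oi22 <- w11 / detom
  n <- ws$n
  os <- ws$obs_subj
  phi <- vi_phi_init(n)
  ad <- adam_state(length(phi))
  set.seed(child_seed(seed, 31))
  for (epoch in seq_len(epochs)) {
    mu1 <- phi[, 1]; mu2 <- phi[, 2]
    l11 <- as.numeric(softplus(phi[, 3])); l21 <- phi[, 4]
    l22 <- as.numeric(softplus(phi[, 5]))
    dmu1 <- dmu2 <- dl11 <- dl21 <- dl22 <- numeric(n)
    for (s in seq_len(n_mc)) {
      e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
      eta1 <- mu1 + l11 * e1
      eta2 <- mu2 + l21 * e1 + l22 * e2
      p <- fast_pred(ws, CL, V1, Q, V2, eta1, eta2)
      v <- vr$siga^2 + (vr$sigp * p$y)^2
      rres <- ws$obs_y - p$y
      dl_dy <- rres / v + vr$sigp^2 * p$y * (rres^2 / v^2 - 1 / v)
      g1 <- rowsum_c(p$G1 * dl_dy, os, n) - (oi11 * eta1 + oi12 * eta2)
      g2 <- rowsum_c(p$G2 * dl_dy, os, n) - (oi12 * eta1 + oi22 * eta2)
      x2 <- e2 / l22
      x1 <- (e1 - l21 * x2) / l11
      gt1 <- g1 + x1
      gt2 <- g2 + x2
      dmu1 <- dmu1 + gt1; dmu2 <- dmu2 + gt2
      dl11 <- dl11 + gt1 * e1
      dl21 <- dl21 + gt2 * e1
      dl22 <- dl22 + gt2 * e2
      if (estimator == "standard") {
        dmu1 <- dmu1 - x1; dmu2 <- dmu2 - x2
        dl11 <- dl11 + (1 / l11 - x1 * e1)
        dl21 <- dl21 - x2 * e1
        dl22 <- dl22 + (1 / l22 - x2 * e2)
      }
    }
    dphi <- cbind(dmu1, dmu2,
                  dl11 * as.numeric(sigmoid(phi[, 3])),
                  dl21,
                  dl22 * as.numeric(sigmoid(phi[, 5]))) / n_mc
    up <- adam_update(ad, as.numeric(phi), -as.numeric(dphi), learning_rate)
    ad <- up$state
    phi <- matrix(up$par, n, 5)
  }
  lapply(seq_len(n), function(i) {
    L <- matrix(c(as.numeric(softplus(phi[i, 3])), phi[i, 4], 0,
                  as.numeric(softplus(phi[i, 5]))), 2, 2)
    variational_posterior(phi[i, 1:2], L)
  })
}
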