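# Objectives: joint density, MAP, FO/FOCE against closed-form
# linear-mixed-model oracles, ELBO against the conjugate toy, and
# agreement between the per-subject reference path and the vectorized
# training path.

test_that("log_joint reduces to the prior without observations and to the stated closed forms", {
  toy <- scalar_toy_pop()
  s_empty <- scalar_toy_subject(numeric(0))
  expect_equal(log_joint(toy, s_empty, 0.3), stats::dnorm(0.3, log = TRUE))
  # one observation, prediction == observation, eta = 0
  pop2 <- population_parameters(NULL, omega_decomposition(c(0.2, 0.3)),
                                residual_model("additive", 1.5),
                                predfun = function(s, eta) list(y = 7, G = matrix(0, 1, 2)))
  s1 <- subject_record(1, list(), dose_events(numeric(0), numeric(0)), 1, 7)
  om <- omega_matrix(pop2$omega)
  expect_equal(log_joint(pop2, s1, c(0, 0)),
               -0.5 * log(2 * pi * 1.5^2) + dcmix:::log_dmvnorm0(c(0, 0), om))
  # scalar toy y = eta + eps, unit variances: hand bivariate density
  toy1 <- scalar_toy_pop(1, 1)
  sy <- scalar_toy_subject(2)
  eta <- 0.7
  expect_equal(log_joint(toy1, sy, eta),
               stats::dnorm(2, eta, 1, log = TRUE) + stats::dnorm(eta, log = TRUE))
})

test_that("MAP estimates: prior mode without data, ridge shrinkage, box activation", {
  toy <- scalar_toy_pop(1, 1)
  expect_equal(map_estimate(toy, scalar_toy_subject(numeric(0))), 0)
  expect_equal(map_estimate(toy, scalar_toy_subject(2)), 1, tolerance = 1e-6)
  expect_equal(map_estimate(toy, scalar_toy_subject(10)), 3)   # clipped at the bound
  # shrinkage factor omega^2 / (omega^2 + sigma^2) for general variances
  toy2 <- scalar_toy_pop(0.5, 1)
  expect_equal(map_estimate(toy2, scalar_toy_subject(1.2)),
               1.2 * 0.25 / (0.25 + 1), tolerance = 1e-6)
})

test_that("FO equals the exact -2 log marginal likelihood of the linear mixed toy", {
  toy <- make_linear_toy()
  expect_equal(fo_objective(toy$pop, toy$subjects), linear_toy_m2ll(toy),
               tolerance = 1e-10)
  # doubling Omega moves the objective exactly as the closed form predicts
  pop2 <- toy$pop
  pop2$omega <- dcmix:::omega_from_matrix(2 * toy$omega)
  expect_equal(fo_objective(pop2, toy$subjects),
               linear_toy_m2ll(toy, omega = 2 * toy$omega), tolerance = 1e-10)
})

test_that("FO reduces to the Sigma-weighted least-squares deviance as Omega -> 0", {
  toy <- make_linear_toy()
  pop0 <- toy$pop
  pop0$omega <- omega_decomposition(c(1e-8, 1e-8))
  ls_dev <- sum(vapply(toy$subjects, function(s) {
    r <- s$obs_values - s$x0
    sum(log(toy$sigma^2) + r^2 / toy$sigma^2) + 3 * log(2 * pi)
  }, 0))
  expect_equal(fo_objective(pop0, toy$subjects), ls_dev, tolerance = 1e-6)
})

test_that("FOCE equals FO at zero modes and stays exact for linear models at any mode", {
  toy <- make_linear_toy()
  eh0 <- matrix(0, length(toy$subjects), 2)
  expect_equal(foce_objective(toy$pop, toy$subjects, eh0),
               fo_objective(toy$pop, toy$subjects), tolerance = 1e-12)
  set.seed(8)
  eh <- matrix(stats::rnorm(2 * length(toy$subjects), 0, 0.3), ncol = 2)
  expect_equal(foce_objective(toy$pop, toy$subjects, eh), linear_toy_m2ll(toy),
               tolerance = 1e-10)
})

test_that("FOCE prefers the generating variance scale in the conjugate toy", {
  # y_ij = eta_i + eps: objective at the true (sigma, omega) should beat
  # a 4x inflated pair for most simulated data sets
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    subs <- lapply(1:40, function(i) {
      scalar_toy_subject(stats::rnorm(1, 0, 1) + stats::rnorm(3, 0, 1), id = i)
    })
    pop_true <- scalar_toy_pop(1, 1)
    pop_infl <- scalar_toy_pop(2, 2)
    eh <- matrix(vapply(seq_along(subs), function(i)
      map_estimate(pop_true, subs[[i]]), 0), ncol = 1)
    wins <- wins + (foce_objective(pop_true, subs, eh) <
                      foce_objective(pop_infl, subs, eh))
  }
  expect_gt(wins, 5)
})

test_that("MSE objective: trivial values and the definitional RMSE identity", {
  pop2 <- population_parameters(NULL, omega_decomposition(c(0.2, 0.3)),
                                residual_model("additive", 1),
                                predfun = function(s, eta) list(y = s$x0, G = matrix(0, length(s$x0), 2)))
  s <- subject_record(1, list(), dose_events(numeric(0), numeric(0)), 1:2, c(5, 3))
  s$x0 <- c(5, 3)
  expect_equal(mse_objective(pop2, list(s)), 0)
  s2 <- s; s2$obs_values <- c(7, 3); s2$x0 <- c(5, 3)
  expect_equal(mse_objective(pop2, list(s2)), 2)  # residuals {2, 0}
  expect_equal(rmse_typical(pop2, list(s2)), sqrt(2))
})

test_that("ELBO is a zero-variance estimator of the evidence at the exact posterior", {
  toy <- scalar_toy_pop(1, 1)
  sy <- scalar_toy_subject(2)
  q_star <- variational_posterior(1, matrix(sqrt(0.5)))
  le <- stats::dnorm(2, 0, sqrt(2), log = TRUE)
  vals <- vapply(1:10, function(k)
    as.numeric(elbo(toy, q_star, sy, n_mc = 1, rng_seed = k)), 0)
  expect_equal(vals, rep(le, 10), tolerance = 1e-12)
  # no observations: at q = prior every draw gives exactly 0 (-KL optimum)
  s0 <- scalar_toy_subject(numeric(0))
  q_pr <- variational_posterior(0, matrix(1))
  expect_equal(as.numeric(elbo(toy, q_pr, s0, n_mc = 7, rng_seed = 3)), 0,
               tolerance = 1e-12)
})

test_that("ELBO lies below the evidence with gap KL(q || posterior)", {
  toy <- scalar_toy_pop(1, 1)
  sy <- scalar_toy_subject(2)
  le <- stats::dnorm(2, 0, sqrt(2), log = TRUE)
  q <- variational_posterior(0.4, matrix(0.9))
  kl <- 0.5 * (0.81 / 0.5 + (1 - 0.4)^2 / 0.5 - 1 + log(0.5 / 0.81))
  set.seed(5)
  est <- mean(vapply(1:4000, function(k)
    as.numeric(elbo(toy, q, sy, n_mc = 1, eps = matrix(stats::rnorm(1)))), 0))
  expect_lt(est, le)
  expect_equal(est, le - kl, tolerance = 0.02)
})

test_that("path-derivative gradient vanishes at the exact posterior; the score-bearing one does not", {
  toy <- scalar_toy_pop(1, 1)
  sy <- scalar_toy_subject(2)
  q_star <- variational_posterior(1, matrix(sqrt(0.5)))
  g <- elbo_grad(toy, q_star, sy, n_mc = 5, estimator = "path_derivative", rng_seed = 2)
  expect_equal(g$dmu, 0, tolerance = 1e-10)
  expect_equal(g$dL[1, 1], 0, tolerance = 1e-10)
  g2 <- elbo_grad(toy, q_star, sy, n_mc = 5, estimator = "standard", rng_seed = 2)
  expect_gt(abs(g2$dmu) + abs(g2$dL[1, 1]), 1e-3)
  # both estimators are unbiased: averaged over many draws they agree
  set.seed(11)
  q2 <- variational_posterior(0.5, matrix(0.8))
  acc <- matrix(0, 2, 2)
  for (k in 1:3000) {
    e <- matrix(stats::rnorm(1))
    acc[1, ] <- acc[1, ] + c(elbo_grad(toy, q2, sy, eps = e)$dmu,
                             elbo_grad(toy, q2, sy, eps = e)$dL[1, 1])
    acc[2, ] <- acc[2, ] + c(elbo_grad(toy, q2, sy, eps = e, estimator = "standard")$dmu,
                             elbo_grad(toy, q2, sy, eps = e, estimator = "standard")$dL[1, 1])
  }
  expect_equal(acc[1, ] / 3000, acc[2, ] / 3000, tolerance = 0.05)
})

test_that("increasing n_mc leaves the ELBO expectation unchanged and shrinks its spread", {
  toy <- scalar_toy_pop(1, 1)
  sy <- scalar_toy_subject(2)
  q <- variational_posterior(0.6, matrix(0.8))
  set.seed(21)
  e1 <- vapply(1:800, function(k) as.numeric(elbo(toy, q, sy, n_mc = 1)), 0)
  e16 <- vapply(1:800, function(k) as.numeric(elbo(toy, q, sy, n_mc = 16)), 0)
  expect_equal(mean(e1), mean(e16), tolerance = 0.03)
  expect_lt(stats::sd(e16), stats::sd(e1) / 2)
})

test_that("vectorized training path agrees with the per-subject reference objectives", {
  pop_data <- cached_sim_pop(10, 3)
  cfg <- training_config("fo", seed = 5)
  skel <- dcmix:::init_skeleton(cfg, dcm_network_spec())
  skel$omega <- omega_decomposition(c(0.2, 0.35), matrix(c(1, 0.6, 0.6, 1), 2, 2))
  ws <- dcmix:::make_workspace(pop_data)
  raw <- dcmix:::pop_to_raw(skel)
  pop <- dcmix:::pop_from_raw(raw, skel)
  expect_equal(dcmix:::fast_obj_grad(raw, skel, ws, "fo")$value,
               fo_objective(pop, pop_data), tolerance = 1e-10)
  expect_equal(dcmix:::fast_obj_grad(raw, skel, ws, "mse")$value,
               mse_objective(pop, pop_data), tolerance = 1e-10)
  set.seed(8)
  eh <- matrix(stats::rnorm(20, 0, 0.2), 10, 2)
  expect_equal(dcmix:::fast_obj_grad(raw, skel, ws, "foce", eh)$value,
               foce_objective(pop, pop_data, eh), tolerance = 1e-10)
  lay <- dcmix:::raw_layout(skel)
  fwd <- dcmix:::net_forward_raw(raw, skel, ws, lay)
  vr <- dcmix:::var_from_raw(raw, lay)
  eh_fast <- dcmix:::fast_map_all(ws, fwd$CL, fwd$V1, fwd$Q, fwd$V2, vr)
  eh_gen <- t(vapply(seq_along(pop_data), function(i)
    map_estimate(pop, pop_data[[i]]), c(0, 0)))
  expect_equal(eh_fast, eh_gen, tolerance = 1e-6)
})

test_that("training gradients match finite differences of the objective", {
  pop_data <- cached_sim_pop(10, 3)
  cfg <- training_config("fo", seed = 5)
  skel <- dcmix:::init_skeleton(cfg, dcm_network_spec())
  skel$omega <- omega_decomposition(c(0.25, 0.3), matrix(c(1, 0.4, 0.4, 1), 2, 2))
  ws <- dcmix:::make_workspace(pop_data)
  raw <- dcmix:::pop_to_raw(skel)
  r <- dcmix:::fast_obj_grad(raw, skel, ws, "fo")
  set.seed(2)
  for (j in sample(length(raw), 8)) {
    rp <- raw; rp[j] <- rp[j] + 1e-5
    rm <- raw; rm[j] <- rm[j] - 1e-5
    fd <- (dcmix:::fast_obj_grad(rp, skel, ws, "fo")$value -
             dcmix:::fast_obj_grad(rm, skel, ws, "fo")$value) / 2e-5
    expect_equal(r$grad[j], fd, tolerance = 1e-3 * max(1, abs(fd)))
  }
  # VI: value matches the reference ELBO for shared draws; the
  # score-bearing gradient matches total finite differences
  n <- ws$n
  set.seed(9)
  phi <- dcmix:::vi_phi_init(n) + matrix(stats::rnorm(n * 5, 0, 0.2), n, 5)
  eps <- array(stats::rnorm(n * 2 * 3), c(n, 2, 3))
  rv <- dcmix:::fast_vi_grad(raw, phi, skel, ws, estimator = "standard", eps = eps)
  pop <- dcmix:::pop_from_raw(raw, skel)
  qs <- lapply(seq_len(n), function(i) variational_posterior(
    phi[i, 1:2], matrix(c(as.numeric(softplus(phi[i, 3])), phi[i, 4], 0,
                          as.numeric(softplus(phi[i, 5]))), 2, 2)))
  val_gen <- sum(vapply(seq_len(n), function(i)
    as.numeric(elbo(pop, qs[[i]], pop_data[[i]], eps = t(eps[i, , ]))), 0))
  expect_equal(-rv$value, val_gen, tolerance = 1e-9)
  for (tst in list(c(2, 1), c(5, 3), c(1, 4), c(7, 5))) {
    pp <- phi; pp[tst[1], tst[2]] <- pp[tst[1], tst[2]] + 1e-6
    pm <- phi; pm[tst[1], tst[2]] <- pm[tst[1], tst[2]] - 1e-6
    fd_loss <- (dcmix:::fast_vi_grad(raw, pp, skel, ws, estimator = "standard", eps = eps)$value -
                  dcmix:::fast_vi_grad(raw, pm, skel, ws, estimator = "standard", eps = eps)$value) / 2e-6
    expect_equal(as.numeric(rv$grad_phi[tst[1], tst[2]]), fd_loss,
                 tolerance = 1e-3 * max(1, abs(fd_loss)))
  }
})

test_that("a non-positive-definite Omega is flagged with a definite error, not a crash", {
  toy <- make_linear_toy(n = 3)
  bad <- toy$pop
  bad$omega$C[1, 2] <- bad$omega$C[2, 1] <- 1.0000001
  expect_error(fo_objective(bad, toy$subjects), "positive definite")
  expect_error(foce_objective(bad, toy$subjects), "positive definite")
  expect_error(log_joint(bad, toy$subjects[[1]], c(0, 0)), "positive definite")
})
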