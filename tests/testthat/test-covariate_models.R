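# Covariate models: leaky softplus, the ground-truth map, the
# multi-branch network and the random-effect transform.

test_that("leaky_softplus matches its closed form and asymptotes", {
  expect_equal(leaky_softplus(0), (1 - 1 / 20) * log(2) / (1 / 10), tolerance = 1e-12)
  expect_equal(leaky_softplus(1e4) / 1e4, 1, tolerance = 1e-3)       # slope -> 1
  expect_equal(leaky_softplus(-1000), -50, tolerance = 1e-6)         # alpha * x
  x <- seq(-50, 50, by = 0.25)
  expect_true(all(diff(leaky_softplus(x)) > 0))                      # monotone
  d <- diff(leaky_softplus(x)) / 0.25
  expect_true(all(d > 1 / 20 & d < 1))                               # slope in (alpha, 1)
})

test_that("ground-truth map reproduces its stated parameter values", {
  z <- true_pk_parameters(list(weight = 70, vwf = 100))
  expect_equal(z[["V1"]], 2.0, tolerance = 1e-12)
  expect_equal(z[["Q"]], 0.15)
  expect_equal(z[["V2"]], 0.75)
  expect_equal(z[["CL"]], 0.1 * (leaky_softplus(200) / 55 + 0.9), tolerance = 1e-12)
  expect_equal(true_pk_parameters(list(weight = 140, vwf = 100))[["V1"]], 4.0,
               tolerance = 1e-12)
})

test_that("random-effect transform: identity at the mode, exp scaling, log-normal median", {
  z <- pk_params(0.4, 2, 0.15, 0.75)
  expect_equal(apply_random_effects(z, c(0, 0)), z)
  z2 <- apply_random_effects(z, c(log(2), 0))
  expect_equal(z2[["CL"]], 0.8, tolerance = 1e-12)
  expect_equal(z2[["V1"]], 2)
  set.seed(1)
  om <- matrix(c(0.037, 0.0113, 0.0113, 0.017), 2, 2)
  eta <- dcmix:::rmvnorm0(1e5, om)
  cls <- z[["CL"]] * exp(eta[, 1])
  expect_equal(stats::median(cls), z[["CL"]], tolerance = 0.01)
})

test_that("branch network: zeroed output weights give a constant, runs are deterministic", {
  theta <- init_network(dcm_network_spec(), seed = 2)
  for (k in seq_along(theta$branches)) theta$branches[[k]]$w2[] <- 0
  covs <- data.frame(weight = c(50, 80, 120), vwf = c(60, 110, 200))
  f <- typical_params(theta, covs)
  expect_equal(f$CL, rep(as.numeric(softplus(theta$bias[["CL"]])), 3))
  expect_equal(f$V1, rep(as.numeric(softplus(theta$bias[["V1"]])), 3))
  th2 <- init_network(dcm_network_spec(), seed = 9)
  a <- branch_forward(th2, list(weight = 75, vwf = 130))
  b <- branch_forward(th2, list(weight = 75, vwf = 130))
  expect_identical(a, b)
})

test_that("network forward equals a hand-composed affine/activation chain", {
  spec <- dcm_network_spec(list(branch_spec("weight", "CL", hidden = 4),
                                branch_spec("weight", "V1", hidden = 4)))
  theta <- init_network(spec, seed = 5)
  w <- 95
  x <- w / 70
  br <- theta$branches[[1]]
  z <- drop(br$W1 %*% x + br$b1)
  hand_pre <- sum((z / (1 + exp(-z))) * br$w2) + theta$bias[["CL"]]
  got <- branch_forward(theta, list(weight = w, vwf = 100))
  expect_equal(got[["CL"]], log(1 + exp(hand_pre)), tolerance = 1e-12)
})

test_that("outputs are invariant to covariates not wired into any branch", {
  spec <- dcm_network_spec(list(branch_spec("weight", "CL"),
                                branch_spec("weight", "V1")))
  theta <- init_network(spec, seed = 3)
  a <- typical_params(theta, data.frame(weight = 70, vwf = 50))
  b <- typical_params(theta, data.frame(weight = 70, vwf = 240))
  expect_equal(a, b)
})

test_that("network backprop matches finite differences of a scalar loss", {
  theta <- init_network(dcm_network_spec(), seed = 12)
  covs <- data.frame(weight = c(55, 82, 130), vwf = c(70, 120, 210))
  loss_of <- function(vec) {
    th <- dcmix:::net_unpack(vec, theta)
    f <- dcmix:::net_forward(th, covs)
    sum(f$CL^2) + sum(3 * f$V1) + 2 * f$Q + f$V2^2
  }
  vec <- dcmix:::net_pack(theta)
  f <- dcmix:::net_forward(theta, covs, cache = TRUE)
  dpre_CL <- 2 * f$CL * as.numeric(sigmoid(f$pre_CL))
  dpre_V1 <- 3 * as.numeric(sigmoid(f$pre_V1))
  dQraw <- 2 * as.numeric(sigmoid(theta$globals[["Q"]]))
  dV2raw <- 2 * f$V2 * as.numeric(sigmoid(theta$globals[["V2"]]))
  g <- dcmix:::net_backprop(theta, f, dpre_CL, dpre_V1, dQraw, dV2raw)
  set.seed(1)
  for (j in sample(length(vec), 15)) {
    vp <- vec; vp[j] <- vp[j] + 1e-6
    vm <- vec; vm[j] <- vm[j] - 1e-6
    expect_equal(g[j], (loss_of(vp) - loss_of(vm)) / 2e-6, tolerance = 1e-4)
  }
})

test_that("covariate-effect summaries: band collapse, truth identity, order statistics", {
  grid <- list(weight = seq(50, 130, by = 20), vwf = seq(50, 250, by = 50))
  one <- visualize_covariate_effects(list(init_network(dcm_network_spec(), seed = 4)), grid)
  expect_equal(one$median, one$lower)
  expect_equal(one$median, one$upper)
  tru <- visualize_covariate_effects(list(dcm_truth_map()), grid)
  wrow <- tru[tru$covariate == "weight" & tru$target == "CL", ]
  expect_equal(wrow$median,
               0.1 * (wrow$value / 70)^0.75 * (leaky_softplus(100 + 100) / 55 + 0.9),
               tolerance = 1e-12)
  # two constant replicates with outputs {1, 3}: pointwise median 2
  const_theta <- function(v) {
    th <- init_network(dcm_network_spec(), seed = 1)
    for (k in seq_along(th$branches)) th$branches[[k]]$w2[] <- 0
    th$bias[] <- softplus_inv(v)
    th
  }
  two <- visualize_covariate_effects(list(const_theta(1), const_theta(3)),
                                     list(weight = c(50, 80, 120)))
  expect_equal(two$median[two$target == "CL"], rep(2, 3))
  expect_error(visualize_covariate_effects(list(), grid), "replicates")
})
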