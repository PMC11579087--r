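# Training loop and experiment grid: determinism, failure isolation,
# toy recovery, config and parameter serialization.

test_that("zero-epoch fits return the initial parameters with an empty trajectory", {
  pop <- cached_sim_pop(8, 11)
  fit <- dcm_fit(training_config("fo", epochs = 0, seed = 2), pop)
  expect_equal(nrow(fit$checkpoints), 0L)
  init <- dcmix:::init_skeleton(fit$config, dcm_network_spec())
  expect_equal(fit$final_pop$omega$S, init$omega$S)
  expect_equal(fit$final_pop$residual$sigma_add, init$residual$sigma_add)
})

test_that("identical config and seed give identical checkpoints; seeds differ otherwise", {
  pop <- cached_sim_pop(8, 11)
  cfg <- training_config("vi", epochs = 50, checkpoint_every = 10,
                         trailing_window = 30, seed = 7)
  f1 <- dcm_fit(cfg, pop)
  f2 <- dcm_fit(cfg, pop)
  expect_identical(f1$checkpoints, f2$checkpoints)
  cfg$seed <- 8
  f3 <- dcm_fit(cfg, pop)
  expect_false(isTRUE(all.equal(f1$checkpoints, f3$checkpoints)))
})

test_that("FOCE runs end to end and refreshes MAP estimates", {
  pop <- cached_sim_pop(8, 11)
  fit <- dcm_fit(training_config("foce", epochs = 12, checkpoint_every = 4,
                                 trailing_window = 8, seed = 3), pop)
  expect_equal(fit$status, "converged")
  expect_equal(dim(fit$eta_hats), c(8L, 2L))
  expect_true(all(abs(fit$eta_hats) <= 3))
  expect_false(all(fit$eta_hats == 0))
})

test_that("a diverging run is flagged as failed and does not abort the grid", {
  pop <- cached_sim_pop(8, 11)
  bad <- dcm_fit(training_config("fo", learning_rate = 1e8, epochs = 30,
                                 checkpoint_every = 10, seed = 2), pop)
  expect_equal(bad$status, "failed")
  expect_true(nzchar(bad$reason))
  # grid with one absurd config still yields rows for every run
  cfgs <- list(fo = training_config("fo", learning_rate = 1e8, epochs = 30,
                                    checkpoint_every = 10, trailing_window = 20),
               mse = training_config("mse", epochs = 30, checkpoint_every = 10,
                                     trailing_window = 20))
  rep <- run_experiment(pop, fold_plan(n_folds = 2, train_size = 5,
                                       replicates_per_fold = 1), cfgs, seed = 4)
  expect_equal(nrow(rep$runs), 4L)
  expect_true(all(rep$runs$status[rep$runs$objective == "fo"] == "failed"))
  expect_true(all(is.na(rep$runs$rmse[rep$runs$objective == "fo"])))
  expect_true(all(is.finite(rep$runs$rmse[rep$runs$objective == "mse"])))
  # MSE rows carry no population-parameter metrics
  expect_false("kl_omega" %in% rep$summary$metric[rep$summary$objective == "mse"])
})

test_that("experiment bookkeeping: one row per (objective, fold, replicate), seeds logged", {
  pop <- cached_sim_pop(30, 11)
  cfgs <- list(mse = training_config("mse", epochs = 20, checkpoint_every = 10,
                                     trailing_window = 10))
  rep <- run_experiment(pop, fold_plan(n_folds = 2, train_size = 10,
                                       replicates_per_fold = 2), cfgs, seed = 5)
  expect_equal(nrow(rep$runs), 4L)
  expect_equal(anyDuplicated(rep$runs$seed), 0L)
  one <- run_experiment(pop, fold_plan(n_folds = 1, train_size = 10,
                                       replicates_per_fold = 1), cfgs, seed = 5)
  expect_equal(one$summary$sd[one$summary$metric == "rmse"], 0)
})

test_that("VI on the scalar conjugate toy recovers the prior SD", {
  set.seed(42)
  subs <- lapply(1:100, function(i) {
    eta <- stats::rnorm(1, 0, 0.8)
    scalar_toy_subject(eta + stats::rnorm(1, 0, 0.5), id = i)
  })
  skel <- scalar_toy_pop(0.4, 0.5)   # sigma known, held at truth
  skel$fix_residual <- TRUE
  fit <- dcm_fit(training_config("vi", epochs = 300, checkpoint_every = 50,
                                 trailing_window = 150, seed = 3, n_mc = 5,
                                 init_q_sd = 0.3), subs, skeleton = skel)
  expect_equal(fit$final_pop$omega$S[1], 0.8, tolerance = 0.15)
})

test_that("configs and fitted parameters round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(objective = "foce", epochs = 40, learning_rate = 0.02,
                            branches = list(list(inputs = "weight", target = "CL", hidden = 8),
                                            list(inputs = "weight", target = "V1", hidden = 8))),
                       f, auto_unbox = TRUE)
  got <- read_model_config(f)
  expect_equal(got$config$objective, "foce")
  expect_equal(got$config$learning_rate, 0.02)
  expect_length(got$model_spec$branches, 2)
  expect_equal(got$model_spec$branches[[1]]$hidden, 8L)
  unlink(f)

  pop <- cached_sim_pop(8, 11)
  fit <- dcm_fit(training_config("fo", epochs = 30, checkpoint_every = 10,
                                 trailing_window = 20, seed = 2), pop)
  fp <- tempfile(fileext = ".json")
  save_fit_params(fit, fp)
  back <- load_fit_params(fp)
  covs <- data.frame(weight = c(60, 100), vwf = c(80, 180))
  expect_equal(typical_params(back$theta, covs),
               typical_params(fit$final_pop$theta, covs), tolerance = 1e-9)
  expect_equal(omega_matrix(back$omega), omega_matrix(fit$final_pop$omega),
               tolerance = 1e-9)
  unlink(fp)
})

test_that("scenario-1 variational fits shrink toward the prior for uninformative subjects", {
  pop <- cached_sim_pop(30, 11)
  pt <- truth_pop_for(pop)
  s0 <- subject_record("empty", list(weight = 70, vwf = 100),
                       dose_events(0, 1750), numeric(0), numeric(0))
  qs <- fit_vi_posteriors(pt, list(s0), epochs = 400, seed = 2)
  expect_equal(qs[[1]]$mu, c(0, 0), tolerance = 0.05)
  expect_equal(tcrossprod(qs[[1]]$L), omega_matrix(pt$omega), tolerance = 0.02)
})
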