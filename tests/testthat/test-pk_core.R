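# Two-compartment engine: closed-form solution vs numerical integration,
# kinetic invariants, parameter sensitivities, and data I/O.

p_ref <- pk_params(0.1, 2.0, 0.15, 0.75)

test_that("bolus initial condition and empty dose list", {
  cs <- predict_concentrations(p_ref, dose_events(0, 1750), c(1e-10, 4))
  expect_equal(cs$conc[1], 87.5, tolerance = 1e-6)  # 1750 IU / 2 L / 10
  cs0 <- predict_concentrations(p_ref, dose_events(numeric(0), numeric(0)), c(0, 4, 24))
  expect_equal(cs0$conc, c(0, 0, 0))
  expect_equal(predict_concentrations(p_ref, dose_events(0, 1750), numeric(0))$conc,
               numeric(0))
})

test_that("analytic solution matches stiff ODE integration (bolus and infusion)", {
  set.seed(42)
  for (k in 1:10) {
    params <- pk_params(exp(stats::runif(1, log(0.05), log(1))),
                        exp(stats::runif(1, log(0.5), log(5))),
                        exp(stats::runif(1, log(0.05), log(0.5))),
                        exp(stats::runif(1, log(0.3), log(3))))
    doses <- dose_events(c(0, stats::runif(1, 1, 10)), c(1750, 1000),
                         c(0, stats::runif(1, 0.5, 3)))
    a <- predict_concentrations(params, doses, c(4, 24, 48))$conc
    b <- ode_oracle(params, doses, c(4, 24, 48))
    expect_equal(a, b, tolerance = 1e-7)
  }
})

test_that("superposition and dose proportionality hold (linear kinetics)", {
  t <- c(2, 10, 30)
  one <- predict_concentrations(p_ref, dose_events(0, 1000), t)$conc
  two <- predict_concentrations(p_ref, dose_events(5, 750, 1), t)$conc
  both <- predict_concentrations(p_ref, dose_events(c(0, 5), c(1000, 750), c(0, 1)), t)$conc
  expect_equal(both, one + two, tolerance = 1e-12)
  scaled <- predict_concentrations(p_ref, dose_events(c(0, 5), 3 * c(1000, 750), c(0, 1)), t)$conc
  expect_equal(scaled, 3 * both, tolerance = 1e-12)
})

test_that("Q -> 0 converges to the one-compartment bolus solution", {
  t <- c(1, 6, 24)
  pq <- pk_params(0.2, 1.5, 1e-9, 0.75)
  got <- predict_concentrations(pq, dose_events(0, 1000), t)$conc
  expect_equal(got, 1000 / 1.5 / 10 * exp(-0.2 / 1.5 * t), tolerance = 1e-6)
})

test_that("short infusions converge to the bolus solution", {
  t <- c(4, 24)
  bol <- predict_concentrations(p_ref, dose_events(0, 1750), t)$conc
  for (d in c(1, 0.1, 1e-3, 1e-6)) {
    inf <- predict_concentrations(p_ref, dose_events(0, 1750, d), t)$conc
    err <- max(abs(inf - bol))
    if (d <= 1e-6) expect_lt(err, 1e-4)
  }
  inf1 <- predict_concentrations(p_ref, dose_events(0, 1750, 1e-3), t)$conc
  inf2 <- predict_concentrations(p_ref, dose_events(0, 1750, 1e-2), t)$conc
  expect_lt(max(abs(inf1 - bol)), max(abs(inf2 - bol)) + 1e-12)
})

test_that("total drug amount decays monotonically after the last dose", {
  doses <- dose_events(c(0, 6), c(1750, 500), c(0, 2))
  out <- ode_oracle(p_ref, doses, seq(9, 72, by = 3), full = TRUE)
  tot <- rowSums(out[out[, "time"] >= 8.5, c("A1", "A2")])
  expect_true(all(diff(tot) < 0))
})

test_that("closed-form CL/V1 sensitivities agree with central differences", {
  set.seed(7)
  for (k in 1:5) {
    p <- c(stats::runif(1, 0.05, 1), stats::runif(1, 0.5, 5),
           stats::runif(1, 0.05, 0.5), stats::runif(1, 0.3, 3))
    tt <- stats::runif(2, 0.5, 60)
    g <- dcmix:::pk_conc_pairs(rep(p[1], 2), rep(p[2], 2), rep(p[3], 2), rep(p[4], 2),
                               c(0, 2), c(1750, 900), c(0, 1.5), tt, grad = TRUE)
    h <- 1e-6
    for (j in 1:2) {
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      fd <- (dcmix:::pk_conc_pairs(rep(pp[1], 2), rep(pp[2], 2), rep(pp[3], 2), rep(pp[4], 2),
                                   c(0, 2), c(1750, 900), c(0, 1.5), tt) -
             dcmix:::pk_conc_pairs(rep(pm[1], 2), rep(pm[2], 2), rep(pm[3], 2), rep(pm[4], 2),
                                   c(0, 2), c(1750, 900), c(0, 1.5), tt)) / (2 * h)
      expect_equal(if (j == 1) g$dCL else g$dV1, fd, tolerance = 1e-5)
    }
  }
})

test_that("invalid parameters and times are rejected", {
  expect_error(pk_params(-0.1, 2, 0.15, 0.75), "positive")
  expect_error(pk_params(0.1, 0, 0.15, 0.75), "positive")
  expect_error(predict_concentrations(p_ref, dose_events(0, 1750), c(-1, 4)), "times")
  expect_error(dose_events(0, -5), "non-negative")
})

test_that("NONMEM-flavoured CSV round-trips a population", {
  pop <- cached_sim_pop(5, 11)
  f <- tempfile(fileext = ".csv")
  write_pk_data(pop, f)
  back <- read_pk_data(f)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$obs_values, pop[[i]]$obs_values, tolerance = 1e-9)
    expect_equal(back[[i]]$doses$amount, pop[[i]]$doses$amount)
    expect_equal(back[[i]]$covariates$weight, pop[[i]]$covariates$weight,
                 tolerance = 1e-9)
  }
  unlink(f)
})
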