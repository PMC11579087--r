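# Shared oracles and fixture builders. Everything is generated in code;
# oracles are kept independent of the implementation paths they check.

# stiff numerical integration of the two-compartment system (deSolve),
# returning central concentration in IU/dL and optionally the state
# trajectory (for mass-balance checks)
ode_oracle <- function(params, doses, times, full = FALSE) {
  k10 <- params[["CL"]] / params[["V1"]]
  k12 <- params[["Q"]] / params[["V1"]]
  k21 <- params[["Q"]] / params[["V2"]]
  # integrate piecewise between dose boundaries so the stiff solver never
  # steps across a rate discontinuity or misses a short infusion window
  bounds <- sort(unique(c(0, times, doses$time,
                          doses$time + doses$duration, max(times))))
  state <- c(A1 = 0, A2 = 0)
  res <- matrix(NA_real_, length(bounds), 3,
                dimnames = list(NULL, c("time", "A1", "A2")))
  res[1, ] <- c(bounds[1], state)
  for (j in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[j]; t1 <- bounds[j + 1L]
    # boluses land at the start of their segment
    hit <- doses$duration == 0 & doses$amount > 0 & abs(doses$time - t0) < 1e-12
    state[1] <- state[1] + sum(doses$amount[hit])
    rate <- 0
    tm <- (t0 + t1) / 2
    for (i in seq_len(nrow(doses))) {
      if (doses$duration[i] > 0 && tm >= doses$time[i] &&
          tm < doses$time[i] + doses$duration[i]) {
        rate <- rate + doses$amount[i] / doses$duration[i]
      }
    }
    deriv <- function(t, A, parms) {
      list(c(rate - (k10 + k12) * A[1] + k21 * A[2], k12 * A[1] - k21 * A[2]))
    }
    out <- deSolve::ode(state, c(t0, t1), deriv, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-11)
    state <- out[nrow(out), c("A1", "A2")]
    res[j + 1L, ] <- c(t1, state)
  }
  if (full) return(res)
  res[match(times, res[, "time"]), "A1"] / params[["V1"]] / 10
}

# linear mixed toy: y_i = x0_i + G_i eta + eps; FO/FOCE are exact here
make_linear_toy <- function(n = 6, seed = 4, sigma = 1.5,
                            omega = matrix(c(0.04, 0.012, 0.012, 0.02), 2, 2)) {
  set.seed(seed)
  subs <- lapply(seq_len(n), function(i) {
    G <- matrix(stats::rnorm(6), 3, 2)
    x0 <- stats::rnorm(3, 10)
    eta <- drop(chol(omega) %*% stats::rnorm(2))
    s <- subject_record(i, list(), dose_events(numeric(0), numeric(0)),
                        1:3, x0 + drop(G %*% eta) + stats::rnorm(3, 0, sigma))
    s$x0 <- x0
    s$G <- G
    s
  })
  pop <- population_parameters(
    NULL, dcmix:::omega_from_matrix(omega), residual_model("additive", sigma),
    predfun = function(s, eta) list(y = s$x0 + drop(s$G %*% eta), G = s$G))
  list(pop = pop, subjects = subs, omega = omega, sigma = sigma)
}

# exact -2 log marginal likelihood of the linear toy
linear_toy_m2ll <- function(toy, omega = NULL, sigma = NULL) {
  om <- if (is.null(omega)) toy$omega else omega
  sg <- if (is.null(sigma)) toy$sigma else sigma
  sum(vapply(toy$subjects, function(s) {
    V <- s$G %*% om %*% t(s$G) + diag(sg^2, 3)
    r <- s$obs_values - s$x0
    ch <- chol(V)
    u <- backsolve(ch, r, transpose = TRUE)
    2 * sum(log(diag(ch))) + sum(u^2) + 3 * log(2 * pi)
  }, 0))
}

# scalar conjugate toy: y = eta + eps, closed-form posterior and evidence
scalar_toy_pop <- function(omega_sd = 1, sigma = 1) {
  population_parameters(
    NULL, omega_decomposition(omega_sd), residual_model("additive", sigma),
    predfun = function(s, eta) list(y = rep(eta[1], length(s$obs_times)),
                                    G = matrix(1, length(s$obs_times), 1)))
}

scalar_toy_subject <- function(y, id = 1) {
  subject_record(id, list(), dose_events(numeric(0), numeric(0)),
                 seq_along(y), y)
}

# small simulated population cached per session
sim_pop_cache <- new.env()
cached_sim_pop <- function(n = 30, seed = 11) {
  key <- paste0("n", n, "s", seed)
  if (is.null(sim_pop_cache[[key]])) {
    sim_pop_cache[[key]] <- simulate_population(
      simulation_design(n_subjects = n), seed = seed)
  }
  sim_pop_cache[[key]]
}

truth_pop_for <- function(population) {
  design <- attr(population, "design")
  population_parameters(dcm_truth_map(),
                        dcmix:::omega_from_matrix(design$omega),
                        design$residual)
}
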