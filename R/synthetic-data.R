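# Synthetic haemophilia-A population generator: covariate sampling from a
# small causal DAG (a stand-in for the external generative covariate
# model, with marginal ranges echoing published patient characteristics),
# weight-based dosing, two-compartment simulation of FVIII levels with
# log-normal inter-individual variability, and the fold/replicate
# resampling plan of the simulation study.

#' Sample synthetic patient covariates
#'
#' Draws age, height, weight, blood group and VWF:Ag from a small DAG:
#' age from a truncated normal; height from age (adult plateau) plus
#' noise; weight log-normally around a height-based mean; blood group
#' categorical; VWF:Ag log-normal with a group-O reduction and a mild age
#' trend. This generator is a synthetic stand-in calibrated to plausible
#' adult haemophilia-A ranges (weight 40-140 kg, VWF:Ag 40-250%), not a
#' reproduction of any fitted covariate model.
#'
#' @param n number of subjects.
#' @param seed integer RNG seed.
#' @return data.frame with columns `age`, `height`, `weight`,
#'   `blood_group`, `vwf`.
#' @export
sample_covariates <- function(n, seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  age <- pmin(pmax(stats::rnorm(n, 45, 15), 12), 77)
  h_mean <- ifelse(age < 18, 150 + (age - 12) * 4.5, 177 - 0.05 * pmax(age - 50, 0))
  height <- pmin(pmax(h_mean + stats::rnorm(n, 0, 7), 148), 198)
  w_mean <- 24 * (height / 100)^2
  weight <- pmin(pmax(exp(log(w_mean) + stats::rnorm(n, 0, 0.18)), 40), 140)
  blood_group <- sample(c("O", "A", "B", "AB"), n, replace = TRUE,
                        prob = c(0.45, 0.40, 0.11, 0.04))
  vwf_mu <- log(118) + 0.002 * (age - 45) + ifelse(blood_group == "O", log(0.75), 0)
  vwf <- pmin(pmax(exp(vwf_mu + stats::rnorm(n, 0, 0.28)), 40), 250)
  data.frame(age = age, height = height, weight = weight,
             blood_group = blood_group, vwf = vwf,
             stringsAsFactors = FALSE)
}

#' Weight-based FVIII dose
#'
#' `25 IU/kg`, rounded to the nearest 250 IU (ties away from zero).
#'
#' @param weight body weight in kg (> 0).
#' @return dose in IU.
#' @export
compute_dose <- function(weight) {
  stopifnot(all(weight > 0))
  250 * round_half_away(25 * weight / 250)
}

#' Simulation design of the synthetic study
#'
#' Defaults reproduce the simulated-population conditions: 500 subjects,
#' a single bolus of 25 IU/kg rounded to 250 IU, samples at 4, 24 and
#' 48 h, `Omega = [0.037, 0.0113; 0.0113, 0.017]`, and additive residual
#' error. The true residual SD is a declared assumption of this
#' simulation design (5 IU/dL by default) and is configurable here.
#'
#' @param n_subjects population size.
#' @param dose_per_kg dose in IU/kg.
#' @param dose_rounding rounding grain in IU.
#' @param obs_times sampling times (h).
#' @param omega 2 x 2 random-effect covariance matrix.
#' @param residual a [residual_model()].
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_subjects = 500, dose_per_kg = 25,
                              dose_rounding = 250, obs_times = c(4, 24, 48),
                              omega = matrix(c(0.037, 0.0113, 0.0113, 0.017), 2, 2),
                              residual = residual_model("additive", sigma_add = 5)) {
  stopifnot(n_subjects > 0, all(obs_times > 0), is_pd(omega))
  structure(list(n_subjects = n_subjects, dose_per_kg = dose_per_kg,
                 dose_rounding = dose_rounding, obs_times = sort(obs_times),
                 omega = omega, residual = residual),
            class = "simulation_design")
}

#' Simulate a synthetic population
#'
#' For each subject: sample covariates, map them through the ground-truth
#' covariate model to typical PK parameters, draw `eta ~ N(0, Omega)` and
#' apply it (`exp(eta1)` on CL, `exp(eta2)` on V1), predict the
#' two-compartment concentrations at the design's sampling times, and add
#' residual noise (concentrations floored at 0). The generating `eta` is
#' stored on each record for recovery checks.
#'
#' @param design a [simulation_design()].
#' @param seed integer RNG seed.
#' @return a `dcm_population` (list of [subject_record()]s) with the
#'   design and true parameters attached as attributes.
#' @export
simulate_population <- function(design = simulation_design(), seed = 1L) {
  cov <- sample_covariates(design$n_subjects, seed = child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  n <- design$n_subjects
  eta <- rmvnorm0(n, design$omega)
  truth <- dcm_truth_map()
  zeta <- typical_params(truth, cov)
  dose <- design$dose_rounding *
    round_half_away(design$dose_per_kg * cov$weight / design$dose_rounding)
  subs <- vector("list", n)
  tt <- design$obs_times
  for (i in seq_len(n)) {
    z <- pk_params(zeta$CL[i] * exp(eta[i, 1]), zeta$V1[i] * exp(eta[i, 2]),
                   zeta$Q, zeta$V2)
    cs <- predict_concentrations(z, dose_events(0, dose[i]), tt)
    v <- resid_variance(design$residual, cs$conc)
    y <- pmax(cs$conc + stats::rnorm(length(tt), 0, sqrt(v)), 0)
    subs[[i]] <- subject_record(
      id = sprintf("sim%04d", i),
      covariates = as.list(cov[i, ]),
      doses = dose_events(0, dose[i]),
      obs_times = tt, obs_values = y,
      true_eta = eta[i, ]
    )
  }
  out <- as_population(subs)
  attr(out, "design") <- design
  attr(out, "true_eta") <- eta
  attr(out, "seed") <- seed
  out
}

#' Fold/replicate resampling plan
#'
#' @param n_folds number of training subsets.
#' @param train_size subjects drawn per fold.
#' @param replicates_per_fold training replicates per fold.
#' @param replacement draw with replacement (the study design); drawing
#'   the whole population without replacement is rejected because it
#'   leaves no test subjects.
#' @return a `fold_plan` list.
#' @export
fold_plan <- function(n_folds = 20, train_size = 60, replicates_per_fold = 5,
                      replacement = TRUE) {
  stopifnot(n_folds >= 1, train_size >= 1, replicates_per_fold >= 1)
  structure(list(n_folds = n_folds, train_size = train_size,
                 replicates_per_fold = replicates_per_fold,
                 replacement = replacement),
            class = "fold_plan")
}

#' Draw training folds
#'
#' Each fold draws `train_size` subjects (with replacement by default);
#' the test set is every subject never drawn into that fold's training
#' multiset.
#'
#' @param population a `dcm_population`.
#' @param plan a [fold_plan()].
#' @param seed integer master seed; per-fold child seeds are derived
#'   deterministically and returned.
#' @return list of folds, each `list(train_idx, test_idx, seed)`.
#' @export
make_folds <- function(population, plan = fold_plan(), seed = 1L) {
  n <- length(population)
  stopifnot(n >= plan$train_size)
  if (!plan$replacement && plan$train_size >= n) {
    stop("make_folds: drawing the whole population without replacement leaves an empty test set")
  }
  lapply(seq_len(plan$n_folds), function(f) {
    fs <- child_seed(seed, 100 + f)
    set.seed(fs)
    tr <- sample.int(n, plan$train_size, replace = plan$replacement)
    list(train_idx = tr, test_idx = setdiff(seq_len(n), tr), seed = fs)
  })
}

#' Write a simulated population to disk
#'
#' Writes the NONMEM-flavoured CSV next to a JSON sidecar holding the
#' design, seed and per-subject true random effects.
#'
#' @param population a simulated `dcm_population`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pk_data(population, file.path(dir, "population.csv"))
  design <- attr(population, "design")
  sidecar <- list(
    seed = attr(population, "seed"),
    n_subjects = length(population),
    obs_times = design$obs_times,
    omega = omega_matrix(design$omega),
    residual = list(kind = design$residual$kind,
                    sigma_add = design$residual$sigma_add,
                    sigma_prop = design$residual$sigma_prop),
    true_eta = attr(population, "true_eta")
  )
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
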