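# Accuracy metrics of the simulation study: RMSE of typical predictions,
# Gaussian KL divergence of the random-effect covariance, variance-
# component errors, log-normal CV conversion, replicate aggregation and
# training-trajectory summaries.

#' RMSE of typical predictions
#'
#' Root mean squared error of the population-level (`eta = 0`)
#' predictions pooled over all observations of the given subjects.
#'
#' @param pop [population_parameters()].
#' @param subjects list of [subject_record()]s (typically a test set).
#' @return RMSE in IU/dL.
#' @export
rmse_typical <- function(pop, subjects) {
  sqrt(mse_objective(pop, subjects))
}

#' KL divergence between centered Gaussians
#'
#' `KL(N(0, omega_est) || N(0, omega_true))`, in nats. The direction is
#' fixed with the estimate first: collapsed variance estimates (the
#' failure mode of unstable conditional estimation) are penalized
#' severely, overdispersed ones mildly.
#'
#' @param omega_est,omega_true positive-definite covariance matrices (or
#'   [omega_decomposition()]s).
#' @return KL divergence in nats (non-negative, 0 iff equal).
#' @export
kl_omega <- function(omega_est, omega_true) {
  a <- omega_matrix(omega_est)
  b <- omega_matrix(omega_true)
  if (!is_pd(a) || !is_pd(b)) {
    stop("kl_omega: both covariance matrices must be positive definite")
  }
  k <- nrow(a)
  0.5 * (sum(diag(solve(b, a))) - k + determinant(b)$modulus[1] -
           determinant(a)$modulus[1])
}

#' Coefficient of variation of a log-normal random effect
#'
#' `CV(%) = sqrt(exp(omega^2) - 1) * 100`.
#'
#' @param omega_marginal_sd marginal SD of the random effect on the log
#'   scale (>= 0).
#' @return CV in percent.
#' @export
cv_percent <- function(omega_marginal_sd) {
  stopifnot(all(omega_marginal_sd >= 0))
  sqrt(exp(omega_marginal_sd^2) - 1) * 100
}

#' Aggregate per-replicate metric values
#'
#' Median and SD over non-failed replicates; non-finite values are
#' counted as failures rather than propagated.
#'
#' @param values numeric vector of per-replicate values (NA/NaN marks a
#'   failed replicate).
#' @return list with `median`, `sd`, `n`, `n_failed`, `status`.
#' @export
aggregate_replicates <- function(values) {
  stopifnot(length(values) >= 1)
  ok <- is.finite(values)
  if (!any(ok)) {
    return(list(median = NA_real_, sd = NA_real_, n = 0L,
                n_failed = sum(!ok), status = "all_failed"))
  }
  v <- values[ok]
  list(median = stats::median(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v), n_failed = sum(!ok), status = "ok")
}

#' Summarize a training trajectory
#'
#' Per-checkpoint series of the objective value, `KL(Omega_hat || Omega)`
#' and the residual-SD estimate, plus final parameters as the mean of the
#' checkpoints falling in a trailing window of epochs. The window mean is
#' taken on the unconstrained parameter scale and transformed afterwards,
#' so the averaged covariance cannot leave the positive-definite cone.
#'
#' @param fit a `dcm_fit` object.
#' @param omega_true optional true covariance for the KL series.
#' @param window trailing window length in epochs (default 500).
#' @return list with `series` (data.frame per checkpoint) and
#'   `final_pop` ([population_parameters()] at the window mean).
#' @export
training_trajectory_summary <- function(fit, omega_true = NULL, window = 500) {
  ck <- fit$checkpoints
  if (nrow(ck) == 0L) stop("training_trajectory_summary: no checkpoints")
  epochs <- fit$checkpoint_epochs
  skel <- fit$skeleton
  has_var <- fit$objective != "mse"
  series <- data.frame(epoch = epochs, objective = fit$checkpoint_values)
  if (has_var) {
    lay <- raw_layout(skel)
    kl <- rep(NA_real_, nrow(ck)); sig <- rep(NA_real_, nrow(ck))
    for (j in seq_len(nrow(ck))) {
      vr <- var_from_raw(ck[j, seq_len(lay$total)], lay)
      sig[j] <- vr$siga
      if (!is.null(omega_true)) {
        om <- matrix(c(vr$s1^2, vr$s1 * vr$s2 * vr$rho,
                       vr$s1 * vr$s2 * vr$rho, vr$s2^2), 2, 2)
        kl[j] <- if (is_pd(om)) kl_omega(om, omega_true) else NA_real_
      }
    }
    series$kl_omega <- kl
    series$sigma_add <- sig
  }
  if (window >= max(epochs)) {
    warning("training_trajectory_summary: window longer than training; using all checkpoints")
    inwin <- rep(TRUE, length(epochs))
  } else {
    inwin <- epochs > max(epochs) - window
  }
  lay <- raw_layout(skel)
  wmean <- colMeans(ck[inwin, seq_len(lay$total), drop = FALSE])
  final_pop <- pop_from_raw(wmean, skel)
  list(series = series, final_pop = final_pop, window_checkpoints = sum(inwin))
}
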