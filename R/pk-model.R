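# Closed-form two-compartment kinetics with bolus and constant-rate
# infusion dosing. Drug amounts are in IU, volumes in L, clearances in
# L/h, times in hours; central concentrations are reported in IU/dL
# (1 IU/L = 0.1 IU/dL, hence the division by 10).
#
# Micro-constants: k10 = CL/V1, k12 = Q/V1, k21 = Q/V2. The central
# concentration after a unit bolus is the biexponential
#   f(t) = [(l1 - k21) e^{-l1 t} - (l2 - k21) e^{-l2 t}] / (l1 - l2)
# with l1, l2 the eigenvalue pair of the 2x2 rate matrix
# (l1 + l2 = k10 + k12 + k21, l1 * l2 = k10 * k21). Infusions integrate
# f; multiple doses superpose (linear kinetics). Everything is written to
# be complex-analytic in (CL, V1, Q, V2) so that complex-step derivatives
# are exact, and closed-form sensitivities w.r.t. CL and V1 (the
# random-effect directions) are returned on request.

IU_L_PER_IU_DL <- 10

#' Two-compartment PK parameter vector
#'
#' @param CL clearance (L/h), `V1` central volume (L), `Q`
#'   inter-compartmental clearance (L/h), `V2` peripheral volume (L).
#' @param V1,Q,V2 see `CL`.
#' @return an object of class `pk_params` (named numeric vector).
#' @export
pk_params <- function(CL, V1, Q, V2) {
  p <- c(CL = CL, V1 = V1, Q = Q, V2 = V2)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("pk_params: CL, V1, Q, V2 must all be finite and strictly positive")
  }
  structure(p, class = "pk_params")
}

#' Dosing events table
#'
#' @param time hours since first dose (>= 0).
#' @param amount dose amount (IU, >= 0).
#' @param duration infusion duration in hours; 0 means an instantaneous
#'   bolus, `d > 0` a constant-rate infusion of `amount / d` IU/h.
#' @return a `data.frame` with columns `time`, `amount`, `duration`.
#' @export
dose_events <- function(time, amount, duration = 0) {
  d <- data.frame(time = as.numeric(time), amount = as.numeric(amount),
                  duration = as.numeric(rep_len(duration, length(time))))
  if (nrow(d) && (any(d$time < 0) || any(d$amount < 0) || any(d$duration < 0))) {
    stop("dose_events: time, amount and duration must be non-negative")
  }
  d
}

# Low-level vectorized kernel. All arguments are equal-length vectors; each
# element is one (dose, observation-time) pair. Returns concentration in
# IU/dL; with grad = TRUE also d/dCL and d/dV1. Complex parameter input is
# supported (times and dose descriptors stay real).
pk_conc_pairs <- function(CL, V1, Q, V2, dose_time, amount, duration, t,
                          grad = FALSE) {
  tau <- t - dose_time
  act <- tau > 0
  zero <- if (is.complex(c(CL[1], V1[1], Q[1], V2[1]))) complex(length(tau)) else numeric(length(tau))
  if (!any(act)) {
    if (grad) return(list(c = zero, dCL = zero, dV1 = zero))
    return(zero)
  }

  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  a <- k10 + k12 + k21
  b <- k10 * k21
  disc2 <- a * a - 4 * b
  # perturbation guard for the measure-zero repeated-root case
  deg <- Re(disc2) < (1e-10 * Re(a))^2
  if (any(deg)) {
    k10 <- k10 * ifelse(deg, 1 + 1e-7, 1)
    a <- k10 + k12 + k21
    b <- k10 * k21
    disc2 <- a * a - 4 * b
  }
  disc <- sqrt(disc2)
  l1 <- (a + disc) / 2
  l2 <- (a - disc) / 2
  dl <- l1 - l2

  is_inf <- duration > 0
  conc <- zero
  if (grad) {
    # chain rule pieces: l_j depend on CL, V1 through k10 and k12
    dl1_dk10 <- 0.5 * (1 + (a - 2 * k21) / disc)
    dl2_dk10 <- 0.5 * (1 - (a - 2 * k21) / disc)
    dl1_dk12 <- 0.5 * (1 + a / disc)
    dl2_dk12 <- 0.5 * (1 - a / disc)
    dl1_dCL <- dl1_dk10 / V1
    dl2_dCL <- dl2_dk10 / V1
    dl1_dV1 <- dl1_dk10 * (-CL / V1^2) + dl1_dk12 * (-Q / V1^2)
    dl2_dV1 <- dl2_dk10 * (-CL / V1^2) + dl2_dk12 * (-Q / V1^2)
    dCL <- zero
    dV1 <- zero
  }

  # unit-bolus response and its l-derivatives at elapsed time tt
  fval <- function(tt, idx) {
    E1 <- exp(-l1[idx] * tt)
    E2 <- exp(-l2[idx] * tt)
    N <- (l1[idx] - k21[idx]) * E1 - (l2[idx] - k21[idx]) * E2
    f <- N / dl[idx]
    out <- list(f = f)
    if (grad) {
      out$dfl1 <- ((1 - tt * (l1[idx] - k21[idx])) * E1 - f) / dl[idx]
      out$dfl2 <- (-(1 - tt * (l2[idx] - k21[idx])) * E2 + f) / dl[idx]
    }
    out
  }
  # running unit-rate infusion response G(tt) = int_0^tt f
  gval <- function(tt, idx) {
    E1 <- exp(-l1[idx] * tt)
    E2 <- exp(-l2[idx] * tt)
    M <- (l1[idx] - k21[idx]) * (1 - E1) / l1[idx] -
      (l2[idx] - k21[idx]) * (1 - E2) / l2[idx]
    g <- M / dl[idx]
    out <- list(f = g)
    if (grad) {
      dM1 <- (k21[idx] / l1[idx]^2) * (1 - E1) +
        (l1[idx] - k21[idx]) / l1[idx] * (tt * E1)
      dM2 <- -((k21[idx] / l2[idx]^2) * (1 - E2) +
                 (l2[idx] - k21[idx]) / l2[idx] * (tt * E2))
      out$dfl1 <- (dM1 - g) / dl[idx]
      out$dfl2 <- (dM2 + g) / dl[idx]
    }
    out
  }

  ib <- which(act & !is_inf)
  if (length(ib)) {
    A <- amount[ib] / (IU_L_PER_IU_DL * V1[ib])
    r <- fval(tau[ib], ib)
    conc[ib] <- A * r$f
    if (grad) {
      dCL[ib] <- A * (r$dfl1 * dl1_dCL[ib] + r$dfl2 * dl2_dCL[ib])
      dV1[ib] <- -conc[ib] / V1[ib] +
        A * (r$dfl1 * dl1_dV1[ib] + r$dfl2 * dl2_dV1[ib])
    }
  }
  ii <- which(act & is_inf)
  if (length(ii)) {
    R <- amount[ii] / duration[ii]
    B <- R / (IU_L_PER_IU_DL * V1[ii])
    r1 <- gval(tau[ii], ii)  # running-infusion response at elapsed time
    g <- r1$f
    gl1 <- if (grad) r1$dfl1 else NULL
    gl2 <- if (grad) r1$dfl2 else NULL
    past <- tau[ii] > duration[ii]
    if (any(past)) {
      idx2 <- ii[past]
      r0 <- gval(tau[idx2] - duration[idx2], idx2)
      g[past] <- g[past] - r0$f
      if (grad) {
        gl1[past] <- gl1[past] - r0$dfl1
        gl2[past] <- gl2[past] - r0$dfl2
      }
    }
    conc[ii] <- B * g
    if (grad) {
      dCL[ii] <- B * (gl1 * dl1_dCL[ii] + gl2 * dl2_dCL[ii])
      dV1[ii] <- -conc[ii] / V1[ii] +
        B * (gl1 * dl1_dV1[ii] + gl2 * dl2_dV1[ii])
    }
  }
  if (grad) list(c = conc, dCL = dCL, dV1 = dV1) else conc
}

#' Predict central-compartment concentrations
#'
#' Noise-free concentration-time profile of the two-compartment model for
#' one subject, superposing all dose events (boluses and constant-rate
#' infusions) analytically.
#'
#' @param params a [pk_params()] vector.
#' @param doses a data.frame from [dose_events()] (may have zero rows).
#' @param times observation times in hours (>= 0).
#' @return a `data.frame` of class `concentration_series` with columns
#'   `time` (h) and `conc` (IU/dL).
#' @export
predict_concentrations <- function(params, doses, times) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  times <- as.numeric(times)
  if (any(times < 0) || any(!is.finite(times))) {
    stop("predict_concentrations: observation times must be finite and >= 0")
  }
  nt <- length(times)
  nd <- nrow(doses)
  if (nd == 0L || nt == 0L) {
    conc <- numeric(nt)
  } else {
    it <- rep(seq_len(nt), times = nd)
    id <- rep(seq_len(nd), each = nt)
    v <- pk_conc_pairs(rep(params[["CL"]], nt * nd), rep(params[["V1"]], nt * nd),
                       rep(params[["Q"]], nt * nd), rep(params[["V2"]], nt * nd),
                       doses$time[id], doses$amount[id], doses$duration[id],
                       times[it])
    conc <- rowsum_c(v, it, nt)
  }
  structure(data.frame(time = times, conc = conc),
            class = c("concentration_series", "data.frame"))
}

#' Read subject data from a NONMEM-flavoured CSV
#'
#' Expected columns: `id`, `time`, `amount`, `duration`, `dv` plus optional
#' covariate columns (`weight`, `vwf`, `age`, `height`, `blood_group`).
#' Rows with a non-missing `dv` are concentration observations (IU/dL);
#' rows with `amount > 0` and empty `dv` are dose events.
#'
#' @param path CSV file path.
#' @return a list of [subject_record()] objects (class `dcm_population`).
#' @export
read_pk_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "amount", "duration", "dv")
  if (!all(need %in% names(df))) {
    stop("read_pk_data: missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  covn <- intersect(c("weight", "vwf", "age", "height", "blood_group"), names(df))
  subs <- lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    isobs <- !is.na(d$dv)
    cov <- as.list(d[1, covn, drop = FALSE])
    subject_record(
      id = d$id[1], covariates = cov,
      doses = dose_events(d$time[!isobs], d$amount[!isobs], d$duration[!isobs]),
      obs_times = d$time[isobs], obs_values = d$dv[isobs]
    )
  })
  structure(unname(subs), class = "dcm_population")
}

#' Write subject data to a NONMEM-flavoured CSV
#'
#' Inverse of [read_pk_data()].
#'
#' @param population a list of [subject_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_data <- function(population, path) {
  rows <- lapply(population, function(s) {
    cov <- s$covariates
    covdf <- as.data.frame(cov[intersect(c("weight", "vwf", "age", "height", "blood_group"), names(cov))],
                           stringsAsFactors = FALSE)
    nd <- nrow(s$doses); no <- length(s$obs_times)
    base <- data.frame(
      id = s$id,
      time = c(s$doses$time, s$obs_times),
      amount = c(s$doses$amount, rep(0, no)),
      duration = c(s$doses$duration, rep(0, no)),
      dv = c(rep(NA_real_, nd), s$obs_values)
    )
    if (ncol(covdf)) base <- cbind(base, covdf[rep(1, nd + no), , drop = FALSE])
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
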