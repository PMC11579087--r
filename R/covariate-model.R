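# The fixed-effects covariate -> PK-parameter map f(x; theta). Two
# interchangeable implementations sit behind the generic typical_params():
# the closed-form ground-truth map used by the simulation, and the
# trainable multi-branch neural network. Both return typical parameters
# zeta; per-subject random effects are applied on top by
# apply_random_effects() (z = g(zeta, eta)).

#' Leaky softplus activation
#'
#' `alpha * x + (1 - alpha) * log(exp(beta * x) + 1) / beta`, a smooth,
#' strictly increasing function interpolating between a line of slope
#' `alpha` (for very negative `x`) and slope 1 (for large `x`). Used by the
#' ground-truth clearance model for the VWF:Ag effect.
#'
#' @param x input (any real; numerically safe for large `|x|`).
#' @param alpha,beta leak and smoothness constants.
#' @return value of the activation.
#' @export
leaky_softplus <- function(x, alpha = 1 / 20, beta = 1 / 10) {
  alpha * x + (1 - alpha) * softplus(x * beta) / beta
}

#' Ground-truth covariate model of the simulated population
#'
#' Closed-form hypothetical FVIII population PK covariate map:
#' `CL = 0.1 * (weight/70)^0.75 * (leaky_softplus(vwf + 100)/55 + 0.9)`,
#' `V1 = 2.0 * (weight/70)`, with global `Q = 0.15` and `V2 = 0.75`, and
#' log-normal random effects `exp(eta1)` on CL and `exp(eta2)` on V1.
#'
#' @param cov named list or one-row data.frame with `weight` (kg) and
#'   `vwf` (%).
#' @param eta length-2 random-effect vector (defaults to the mode, 0).
#' @return a [pk_params()] vector.
#' @export
true_pk_parameters <- function(cov, eta = c(0, 0)) {
  zeta <- typical_params(dcm_truth_map(), data.frame(weight = cov$weight, vwf = cov$vwf))
  apply_random_effects(pk_params(zeta$CL, zeta$V1, zeta$Q, zeta$V2), eta)
}

#' The truth map as a fixed-effects object
#'
#' Wraps the closed-form simulation covariate model in the same interface
#' as a trainable network, so it can drive simulation, MCMC scenario
#' definitions and covariate-effect plots.
#'
#' @return an object of class `dcm_truth`.
#' @export
dcm_truth_map <- function() structure(list(), class = "dcm_truth")

#' Typical PK parameters for a table of covariates
#'
#' @param theta a fixed-effects object (`dcm_truth` or `dcm_network`).
#' @param covariates data.frame with one row per subject.
#' @param ... unused.
#' @return list of vectors `CL`, `V1`, `Q`, `V2` (length `nrow(covariates)`
#'   for CL and V1; Q and V2 are scalars shared across subjects).
#' @export
typical_params <- function(theta, covariates, ...) UseMethod("typical_params")

#' @export
typical_params.dcm_truth <- function(theta, covariates, ...) {
  w <- covariates$weight
  v <- covariates$vwf
  list(CL = 0.1 * (w / 70)^0.75 * (leaky_softplus(v + 100) / 55 + 0.9),
       V1 = 2.0 * (w / 70), Q = 0.15, V2 = 0.75)
}

#' Apply random effects to typical parameters
#'
#' `z = g(zeta, eta)`: clearance is multiplied by `exp(eta1)` and the
#' central volume by `exp(eta2)`; Q and V2 carry no random effect.
#'
#' @param zeta typical parameters ([pk_params()]).
#' @param eta length-2 numeric vector.
#' @return individualized [pk_params()].
#' @export
apply_random_effects <- function(zeta, eta) {
  stopifnot(length(eta) == 2, all(is.finite(eta)))
  pk_params(zeta[["CL"]] * exp(eta[1]), zeta[["V1"]] * exp(eta[2]),
            zeta[["Q"]], zeta[["V2"]])
}

## ---------------------------------------------------------------------
## Multi-branch network
## ---------------------------------------------------------------------

#' Branch specification
#'
#' One branch of a multi-branch covariate network: a one-hidden-layer
#' fully connected net from a subset of covariates to a single structural
#' parameter, so that each covariate effect is learned in isolation and
#' can be visualized directly.
#'
#' @param inputs character vector of covariate names (subset of
#'   `"weight"`, `"vwf"`).
#' @param target `"CL"` or `"V1"`.
#' @param hidden hidden-layer width.
#' @return a `branch_spec` list.
#' @export
branch_spec <- function(inputs, target = c("CL", "V1"), hidden = 16L) {
  target <- match.arg(target)
  stopifnot(length(inputs) >= 1, hidden >= 1)
  structure(list(inputs = inputs, target = target, hidden = as.integer(hidden)),
            class = "branch_spec")
}

#' Multi-branch network specification
#'
#' The default wiring matches the simulation-study architecture: weight is
#' connected to CL and V1, VWF:Ag to CL, and Q and V2 are estimated as
#' global (covariate-free) parameters. Covariates are normalized by fixed
#' constants before entering the branches (weight/70, vwf/100).
#'
#' @param branches list of [branch_spec()]s.
#' @param normalization named vector of divisors applied to raw covariates.
#' @return a `dcm_network_spec` object.
#' @export
dcm_network_spec <- function(branches = list(
                               branch_spec("weight", "CL"),
                               branch_spec("vwf", "CL"),
                               branch_spec("weight", "V1")),
                             normalization = c(weight = 70, vwf = 100)) {
  targets <- vapply(branches, `[[`, "", "target")
  stopifnot(all(c("CL", "V1") %in% targets))
  structure(list(branches = branches, normalization = normalization),
            class = "dcm_network_spec")
}

#' Initialize network weights
#'
#' Hidden weights are drawn from N(0, 1/fan_in); hidden biases start at
#' zero; output biases are set so that the softplus-transformed parameters
#' start near plausible typical values (CL near 0.1 L/h, V1 near 2 L, and
#' the softplus-constrained globals Q near 0.2 L/h and V2 near 1 L).
#'
#' @param spec a [dcm_network_spec()].
#' @param seed integer RNG seed for the draw.
#' @return a `dcm_network` fixed-effects object.
#' @export
init_network <- function(spec, seed = 1L) {
  set.seed(seed)
  branches <- lapply(spec$branches, function(b) {
    nin <- length(b$inputs)
    h <- b$hidden
    list(W1 = matrix(stats::rnorm(h * nin, 0, sqrt(1 / nin)), h, nin),
         b1 = numeric(h),
         w2 = stats::rnorm(h, 0, sqrt(1 / h)),
         spec = b)
  })
  structure(list(branches = branches,
                 bias = c(CL = softplus_inv(0.1), V1 = softplus_inv(2)),
                 globals = c(Q = softplus_inv(0.2), V2 = softplus_inv(1)),
                 normalization = spec$normalization,
                 spec = spec),
            class = "dcm_network")
}

# normalized input matrix for one branch
branch_inputs <- function(theta, covariates, b) {
  xs <- vapply(b$spec$inputs, function(nm) {
    covariates[[nm]] / theta$normalization[[nm]]
  }, numeric(nrow(covariates)))
  matrix(xs, nrow = nrow(covariates))
}

# forward pass over a covariate table; optionally keep caches for backprop
net_forward <- function(theta, covariates, cache = FALSE) {
  if (any(!is.finite(unlist(lapply(theta$branches, function(br) c(br$W1, br$b1, br$w2)))))) {
    stop("dcm_network: non-finite weights encountered")
  }
  n <- nrow(covariates)
  pre <- list(CL = rep(theta$bias[["CL"]], n), V1 = rep(theta$bias[["V1"]], n))
  caches <- if (cache) vector("list", length(theta$branches)) else NULL
  for (k in seq_along(theta$branches)) {
    br <- theta$branches[[k]]
    Xb <- branch_inputs(theta, covariates, br)
    Z <- sweep(Xb %*% t(br$W1), 2, br$b1, `+`)
    H <- swish(Z)
    out <- drop(H %*% br$w2)
    tgt <- br$spec$target
    pre[[tgt]] <- pre[[tgt]] + out
    if (cache) caches[[k]] <- list(Xb = Xb, Z = Z, H = H)
  }
  res <- list(pre_CL = pre$CL, pre_V1 = pre$V1,
              CL = as.numeric(softplus(pre$CL)), V1 = as.numeric(softplus(pre$V1)),
              Q = as.numeric(softplus(theta$globals[["Q"]])),
              V2 = as.numeric(softplus(theta$globals[["V2"]])))
  if (cache) res$caches <- caches
  res
}

#' @export
typical_params.dcm_network <- function(theta, covariates, ...) {
  f <- net_forward(theta, covariates)
  list(CL = f$CL, V1 = f$V1, Q = f$Q, V2 = f$V2)
}

#' Evaluate the branch network for one covariate vector
#'
#' @param theta a `dcm_network` object.
#' @param cov named list with the covariates the network uses.
#' @return a [pk_params()] vector of typical parameters.
#' @export
branch_forward <- function(theta, cov) {
  f <- typical_params(theta, as.data.frame(cov[c("weight", "vwf")]))
  pk_params(f$CL[1], f$V1[1], f$Q, f$V2)
}

# Backpropagate d(loss)/d(pre_CL), d(loss)/d(pre_V1) (vectors over
# subjects) plus d(loss)/d(global raw params) into a flat gradient laid
# out like net_pack().
net_backprop <- function(theta, cache, dpre_CL, dpre_V1, dQraw = 0, dV2raw = 0) {
  gb <- vector("list", length(theta$branches))
  for (k in seq_along(theta$branches)) {
    br <- theta$branches[[k]]
    cc <- cache$caches[[k]]
    dpre <- if (br$spec$target == "CL") dpre_CL else dpre_V1
    dw2 <- drop(crossprod(cc$H, dpre))
    dH <- outer(dpre, br$w2)
    dZ <- dH * swish_grad(cc$Z)
    dW1 <- crossprod(dZ, cc$Xb)
    db1 <- colSums(dZ)
    gb[[k]] <- list(W1 = dW1, b1 = db1, w2 = dw2)
  }
  c(unlist(lapply(gb, function(g) c(g$W1, g$b1, g$w2)), use.names = FALSE),
    sum(dpre_CL), sum(dpre_V1), dQraw, dV2raw)
}

# flat parameter vector <-> structured network
net_pack <- function(theta) {
  c(unlist(lapply(theta$branches, function(br) c(br$W1, br$b1, br$w2)), use.names = FALSE),
    theta$bias[["CL"]], theta$bias[["V1"]],
    theta$globals[["Q"]], theta$globals[["V2"]])
}

net_unpack <- function(vec, skeleton) {
  th <- skeleton
  pos <- 0L
  for (k in seq_along(th$branches)) {
    br <- th$branches[[k]]
    nW1 <- length(br$W1); nb1 <- length(br$b1); nw2 <- length(br$w2)
    th$branches[[k]]$W1 <- matrix(vec[pos + seq_len(nW1)], nrow(br$W1), ncol(br$W1))
    pos <- pos + nW1
    th$branches[[k]]$b1 <- vec[pos + seq_len(nb1)]; pos <- pos + nb1
    th$branches[[k]]$w2 <- vec[pos + seq_len(nw2)]; pos <- pos + nw2
  }
  th$bias <- c(CL = vec[pos + 1], V1 = vec[pos + 2])
  th$globals <- c(Q = vec[pos + 3], V2 = vec[pos + 4])
  th
}

#' Learned covariate effects over a grid, with replicate bands
#'
#' Evaluates, for every branch of the network, the target structural
#' parameter over a grid of the branch's covariate (other covariates held
#' at reference values), for each fitted replicate, and summarizes the
#' pointwise median and a 95% band across replicates.
#'
#' @param theta_samples list of fitted fixed-effects objects (one per
#'   training replicate); `dcm_truth` objects are accepted too.
#' @param covariate_grid named list of grid vectors, e.g.
#'   `list(weight = seq(40, 140, 5), vwf = seq(40, 250, 10))`.
#' @param reference named list of reference covariate values used for the
#'   covariates not being varied.
#' @return data.frame with columns `target`, `covariate`, `value`,
#'   `median`, `lower`, `upper`.
#' @export
visualize_covariate_effects <- function(theta_samples, covariate_grid,
                                        reference = list(weight = 70, vwf = 100)) {
  if (length(theta_samples) == 0) stop("visualize_covariate_effects: no replicates given")
  combos <- list(c("weight", "CL"), c("vwf", "CL"), c("weight", "V1"))
  out <- list()
  for (cb in combos) {
    covn <- cb[1]; tgt <- cb[2]
    grid <- covariate_grid[[covn]]
    if (is.null(grid)) next
    covdf <- data.frame(weight = rep(reference$weight, length(grid)),
                        vwf = rep(reference$vwf, length(grid)))
    covdf[[covn]] <- grid
    vals <- vapply(theta_samples, function(th) {
      f <- typical_params(th, covdf)
      as.numeric(f[[tgt]])
    }, numeric(length(grid)))
    vals <- matrix(vals, nrow = length(grid))
    out[[length(out) + 1L]] <- data.frame(
      target = tgt, covariate = covn, value = grid,
      median = apply(vals, 1, stats::median),
      lower = apply(vals, 1, stats::quantile, 0.025),
      upper = apply(vals, 1, stats::quantile, 0.975)
    )
  }
  do.call(rbind, out)
}
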