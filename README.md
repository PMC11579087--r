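# dcmix — mixed-effects estimation for deep compartment models

`dcmix` is an R package for population pharmacokinetic (PK) modelling
with *deep compartment models*: a mechanistic two-compartment kinetic
model whose covariate→parameter map is a multi-branch neural network,
combined with classical per-subject random effects. It is aimed at
pharmacometricians and methods researchers who want to compare how
different estimation objectives behave when fixed effects are learned
by gradient descent — on simulated factor-VIII (FVIII) data where the
ground truth is known.

## The model

For subject *i* with covariates *x*, doses *I* and concentrations *y*:

    y_i(t) = A(t; z_i, I_i) + ε,      ε  ~ N(0, Σ)
    z_i    = g(ζ_i, η_i),             η_i ~ N(0, Ω)
    ζ_i    = f(x_i; θ)

`A` is the closed-form two-compartment model with parameters
(CL, V1, Q, V2); `f` is a multi-branch network (weight → CL, weight →
V1, VWF:Ag → CL by default, with global Q and V2); random effects act
as `exp(η₁)` on CL and `exp(η₂)` on V1. Four training objectives are
implemented over this model:

* **MSE** — typical-prediction least squares (no population parameters);
* **FO** — first-order marginal likelihood, linearized at `η = 0`;
* **FOCE** — first-order *conditional* estimation, linearized at each
  subject's MAP estimate (box-constrained BFGS, `η ∈ [−3, 3]`,
  refreshed every epoch), in interaction and no-interaction
  formulations;
* **VI** — variational inference with per-subject full-rank Gaussian
  posteriors and the reparametrized ELBO (3 Monte-Carlo samples),
  with both the standard and the path-derivative gradient estimator.

A No-U-Turn sampler provides MCMC reference posteriors for validating
the variational approximations (2-Wasserstein comparison), and a
synthetic-population generator plus a fold×replicate harness reproduce
a complete simulation study with accuracy metrics (held-out RMSE of
typical predictions, `KL(Ω̂ ‖ Ω)`, variance-component MAEs,
`CV(%) = √(exp(ω²) − 1)·100`).

## Worked example

Simulate a 500-subject virtual haemophilia-A population (single
25 IU/kg bolus, samples at 4/24/48 h), train a VI model on one
60-subject fold, and evaluate it on the held-out subjects:

```r
library(dcmix)

pop  <- simulate_population(simulation_design(n_subjects = 500), seed = 1)
fold <- make_folds(pop, fold_plan(n_folds = 1, train_size = 60), seed = 2)[[1]]
fit  <- dcm_fit(training_config("vi", epochs = 1000, seed = 3),
                pop[fold$train_idx])
fit
#> <dcm_fit> vi | 60 subjects | 40 checkpoints | status: converged
fit$final_pop
#> <population_parameters> K = 2 | residual: additive (sigma_add = 3.55, sigma_prop = 0)
#>   omega S: 0.1786 0.3515
rmse_typical(fit$final_pop, pop[fold$test_idx])
#> [1] 5.13
kl_omega(omega_matrix(fit$final_pop$omega),
         omega_matrix(attr(pop, "design")$omega))
#> [1] 2.429
branch_forward(fit$final_pop$theta, list(weight = 70, vwf = 100))
#>    CL    V1     Q    V2
#> 0.337 2.920 0.145 2.193
```

Reading the numbers: the held-out RMSE of typical predictions is
5.13 IU/dL — essentially the generator's additive noise floor of
5 IU/dL, i.e. the covariate model explains what is explainable. The
first marginal SD of the random effects (CL, 0.179) lands close to the
generating √0.037 ≈ 0.192, while the V1 component and the residual SD
do not: under the generator's default noise level the 24 h and 48 h
samples sit below the noise floor, so those components are barely
identified — the KL of 2.4 nats quantifies that, and the package's
vignette analyses it in detail. Posterior *shapes*, by contrast, are
recovered accurately: `sample_reference()` + `compare_posteriors()`
show the path-derivative VI posteriors within a median 2-Wasserstein
distance of ~0.03 of the NUTS reference (versus ~0.08 for the standard
estimator).

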