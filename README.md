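# jointgrowth

Joint and two-stage models for childhood growth trajectories and a distal
outcome.

Cohort studies often relate repeated childhood height measurements to an
adult outcome such as systolic blood pressure (BP). Two quantities are of
interest: the **unconditional** association of birth length with the
outcome, α₁, and the **conditional** association of the linear growth rate
with the outcome given birth length, α₄. Because birth length and growth
rate are latent — height is measured with error at jittered ages — the
choice of first-stage estimator determines both the bias of these
associations and the coverage of their confidence intervals.

`jointgrowth` provides, under one roof:

* a seeded cohort simulator: heights from the random-intercept/random-slope
  model `H_ij = β0 + u0j + (β1 + u1j)·Age_ij + e_hij`, outcome
  `BP_j = γ0 + α3·u0j + α4·u1j + e_BPj`, with the implied total effect
  `α1 = α3 + α4·ρ·σu1/σu0`;
* two-stage estimators: two-point summaries, per-individual least squares,
  and univariate multilevel models whose BLUP residuals are used either
  shrunken or re-inflated via the lower-Cholesky transform
  `T = L_Ω L_S⁻¹` that makes their sample covariance match the fitted
  random-effect covariance exactly;
* a bivariate joint multilevel model (heights + outcome sharing a 3×3
  random-effect covariance), simultaneous three-component re-inflation,
  moment-based recovery of (α₁, α₃, α₄) from the fitted covariance, and a
  cluster bootstrap that restores nominal interval coverage;
* a latent growth curve SEM (individual-age loadings by default — an exact
  reparameterisation of the bivariate model with delta-method standard
  errors from the Fisher information; fixed mean-age loadings optional);
* a Monte-Carlo scenario engine reporting relative bias (%) and empirical
  coverage (%) of α₁ and α₄ per method across parameter sweeps.

Model fitting is maximum likelihood via Fisher scoring on the variance
scale (the IGLS scheme) in compiled code; a J = 1000 cohort fits in about
20 ms, so full scenario sweeps and bootstrap studies run in minutes on one
core.

## Worked example

```r
library(jointgrowth)

sched <- draw_age_schedule(n_individuals = 1000, seed = 1)
dat <- simulate_trajectories(sched, growth_params(), outcome_params(), seed = 2)

# two-stage: univariate multilevel model with re-inflated residuals
fit <- fit_univariate_lmm(dat)
res <- inflate_residuals(blup_residuals(fit, dat), fit$omega)
second_stage(estimates_from_residuals(fit, res), dat$bp)
#>   parameter  estimate        se     ci_low   ci_high       method ci_kind
#> 1    alpha1 0.3272471 0.1273350 0.07767058 0.5768236 mlm_inflated    wald
#> 2    alpha3 0.2947198 0.1271512 0.04550355 0.5439361 mlm_inflated    wald
#> 3    alpha4 1.9168841 0.5975080 0.74576844 3.0879998 mlm_inflated    wald

# joint model: SEM standard errors propagate first-stage uncertainty
fit_sem_conditional(dat)
#> Latent growth SEM (conditional, individual_ages loadings)
#>   converged: TRUE, loglik -16314.9381
#>   alpha3 = 0.2429 (SE 0.1514), alpha4 = 2.1556 (SE 0.6713)
fit_sem_unconditional(dat)
#> Latent growth SEM (unconditional, individual_ages loadings)
#>   converged: TRUE, loglik -16314.9381
#>   alpha1 = 0.2794 (SE 0.1497)
```

On this dataset the truth is α₁ = 0.54, α₄ = 2.0 (with sampling SDs around
0.15 and 0.74 at J = 1000, so the single-dataset estimates above are one
draw, not a verdict). The Monte-Carlo engine is the verdict:

```r
scn <- scenario("baseline", n_replicates = 50, master_seed = 1)
run_scenario(scn, methods = c("ols", "mlm_inflated", "sem"))
#> Scenario results (relative bias % / coverage %)
#>  scenario grid_value       method parameter truth rel_bias_pct mc_se_bias coverage_pct mc_se_cov n_converged n_replicates
#>  baseline         NA          ols    alpha1  0.54       -25.46       2.39           80      5.66          50           50
#>  baseline         NA          ols    alpha4  2.00         0.85       4.00           94      3.36          50           50
#>  baseline         NA mlm_inflated    alpha1  0.54         3.79       2.80           98      1.98          50           50
#>  baseline         NA mlm_inflated    alpha4  2.00       -16.14       4.47           92      3.84          50           50
#>  baseline         NA          sem    alpha1  0.54         3.10       3.30           98      1.98          50           50
#>  baseline         NA          sem    alpha4  2.00        -3.73       5.11           96      2.77          50           50
```

Read: per-individual least squares attenuates the birth-length association
(−25% bias, 80% coverage); re-inflated multilevel residuals repair α₁ but
bias α₄ toward the null; the SEM/joint model is close to unbiased for both
with near-nominal coverage. Scenario names `sigma_u0`, `sigma_u1`,
`sigma_eh`, `rho_u01`, `sigma_ebp` sweep the corresponding parameter over
its default grid.

A thin command-line front end is installed with the package
(`system.file("cli", "growthsim.R", package = "jointgrowth")`) with
subcommands `run`, `bootstrap-coverage` and `simulate`; see the header of
that script for usage. The methods vignette (`vignettes/methods.Rmd`)
documents the models, the re-inflation algebra, the SEM equivalences and
all numerical choices.

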