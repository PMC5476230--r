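---
title: "Estimating growth-outcome associations: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating growth-outcome associations: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointgrowth)
```

## The scientific problem

Cohort studies of early-life growth often ask two questions about a later
health outcome such as adult systolic blood pressure (BP): what is the
*total* (unconditional) association of birth size with the outcome, and what
is the association of the *growth rate* with the outcome once birth size is
accounted for? Height is measured repeatedly in childhood with measurement
error and at somewhat irregular ages, so the per-individual birth length and
growth rate are latent quantities. How one estimates those latent summaries
— and whether one models the outcome jointly with the trajectories —
determines whether the association estimates are biased and whether their
confidence intervals have the advertised coverage. This package implements
the competing estimators and a Monte-Carlo engine to measure exactly that.

## Generating model

Heights follow a linear random-intercept/random-slope growth model:

$$H_{ij} = \beta_0 + u_{0j} + (\beta_1 + u_{1j})\,\mathrm{Age}_{ij} + e_{hij},
\qquad (u_{0j}, u_{1j}) \sim N(0, \Omega_u),\quad
e_{hij} \sim N(0, \sigma^2_{eh}),$$

and the distal outcome is linear in the individual deviations:

$$BP_j = \gamma_0 + \alpha_3 u_{0j} + \alpha_4 u_{1j} + e_{BPj},
\qquad e_{BPj} \sim N(0, \sigma^2_{eBP}).$$

$\alpha_3$ and $\alpha_4$ are *conditional* effects. The *unconditional*
(total) birth-length association, the second quantity of interest, follows
from the joint normality of the random effects:

$$\alpha_1 = \alpha_3 + \alpha_4\,\rho_{u01}\,\sigma_{u1}/\sigma_{u0},$$

implemented in `true_alpha1()`. At the default parameters
($\alpha_3 = 0.5$, $\alpha_4 = 2$, $\rho = 0.1$, $\sigma_{u1} = 0.5$,
$\sigma_{u0} = 2.5$) this equals $0.54$ mmHg/cm.

### Default study conditions

The generator defaults describe a medium-to-large cohort measured at birth
and at roughly 2.5, 5, 7.5 and 10 years: $J = 1000$ individuals, five
occasions with age jitter SD 0.5 y except at birth (0.025 y, i.e. ~95% of
birth lengths measured within two weeks of birth), $\beta_0 = 50$ cm,
$\beta_1 = 9$ cm/y, $\sigma_{u0} = 2.5$ cm, $\sigma_{u1} = 0.5$ cm/y,
$\rho_{u01} = 0.1$, $\sigma_{eh} = 2$ cm, $\gamma_0 = 120$ mmHg,
$\sigma_{eBP} = 10$ mmHg. The scenario engine sweeps one parameter at a
time over fixed grids (`scenario()`), holding the rest at these defaults.

Two design details matter more than they look:

* **A single age draw.** One realised age schedule is drawn per scenario
  suite and reused across all replicates (`redraw_ages = FALSE`), mirroring
  designs in which the measurement protocol is a fixed property of the
  cohort. Consequences of this choice are discussed under the SEM below.
* **Monotonicity by redraw.** Individuals whose drawn ages are not strictly
  increasing are redrawn entirely rather than sorted; sorting would distort
  the per-occasion marginal age distributions. At the default jitter the
  redraw probability is about $2 \times 10^{-4}$ per individual.

Seeds are managed by `derive_seed()`: a master seed plus a path of labels
(scenario, grid index, replicate, stream) yields an independent stream per
component, so e.g. changing `sigma_ebp` leaves the simulated heights of the
same replicate untouched, and any single replicate can be regenerated in
isolation. Replicates are therefore order-independent and trivially
parallelisable, although the engine runs serially.

## The estimators

**Two-point ("simple") summaries** (`simple_summaries()`): birth length is
the first observed height, growth rate the secant slope between last and
first occasions. The first height carries its full measurement error, so
the variance of the birth-length summary is inflated by $\sigma^2_{eh}$,
attenuating the second-stage slope toward the null; the shared $H_{1j}$
term couples the two summaries (mathematical coupling), distorting the
conditional coefficient in a direction that depends on the variance ratio
and correlation.

**Per-individual least squares** (`ols_summaries()`): closed-form
intercept/slope per individual. Unbiased per individual, but the
between-individual variance of the estimates adds the OLS sampling
variance, again attenuating the unconditional association.

**Univariate multilevel model** (`fit_univariate_lmm()` +
`blup_residuals()`): maximum-likelihood mixed model; the empirical-Bayes
BLUPs are shrunken toward the population mean, so their sample covariance
*understates* $\Omega_u$. Using shrunken residuals in the second stage
leaves the conditional coefficients unbiased (shrinkage is consistent
across both components) but biases the unconditional coefficient away from
the null. Re-inflation (`inflate_residuals()`) transforms the centred
residuals by $T = L_\Omega L_S^{-1}$ (lower-triangular Cholesky factors of
the target and of the denominator-$J$ sample covariance, means re-added
afterwards) so that their sample covariance equals $\hat\Omega_u$ exactly.
With lower factors the inflated birth-length residual is a pure positive
rescaling of the shrunken one — which is why inflation repairs the
unconditional birth-length association — while the growth-rate residual
becomes a mixture, which is why inflation *damages* the conditional
growth-rate association (bias toward the null, largest when
$\sigma_{u1}$ is small). The `orientation = "upper"` flag exposes the
reverse-ordered factorisation, which mixes the slope into the birth-length
residual and breaks the repair; it exists for exactly that contrast
experiment.

**Bivariate joint model** (`fit_bivariate_lmm()`): heights and the outcome
are stacked per individual; the outcome row has no occasion-level residual
— its variance and its covariances with intercept and slope live in a
$3 \times 3$ random-effect covariance. The full pipeline (fit, BLUPs,
simultaneous three-component re-inflation, second stage on the *estimated*
outcome) gives point estimates that are exact moment transforms of
$\hat\Omega_u$ (`alpha_from_omega()`): the two-stage arithmetic and the
moment estimator coincide by construction, a property the test suite
asserts to $10^{-8}$. The second-stage OLS standard errors ignore the
uncertainty in $\hat\Omega_u$, hence the characteristic ~90% coverage;
`bootstrap_joint()` repairs this by resampling individuals with
replacement and rerunning the entire pipeline per resample (normal and
percentile intervals both reported).

**Structural equation model** (`fit_sem_conditional()` /
`fit_sem_unconditional()`): latent birth-length and growth-rate factors
with slope loadings equal to the measurement ages, and a structural
regression of the outcome on the factors. With loadings at each
individual's observed ages the SEM is an exact reparameterisation of the
bivariate joint model; the package exploits this and, by default, fits it
through the same scoring algorithm, reading the structural coefficients off
the fitted covariance and their standard errors off the inverse Fisher
information by the delta method (mean and covariance parameters are
information-orthogonal in Gaussian models, so the blocks separate). A
`direct` engine maximises the SEM parameterisation itself; the test suite
verifies both routes agree in likelihood and coefficients. The SEM thus
shares the joint model's point estimates while propagating first-stage
uncertainty into the SEs — its intervals attain nominal coverage where the
two-stage joint pipeline undercovers.

### The unconditional SEM refit

For the total birth-length effect the structural model regresses the
outcome on the birth-length factor alone. Specifying this naively (no
growth-rate path, no residual covariance) would leave the model unable to
represent the outcome/growth-rate covariance and would distort the
coefficient. The package instead frees the covariance between the
structural residual and the growth-rate factor (parameterised through the
component of the growth factor orthogonal to birth length, which keeps the
implied covariance positive definite). This makes the unconditional model
an exact reparameterisation of the conditional one — identical maximised
likelihood — whose birth-length coefficient is precisely the total effect
$\alpha_3 + \alpha_4 \psi_{12}/\psi_{11}$, now with a direct standard
error. `alpha1_from_sem()` applies the same transform to a conditional fit
without an SE.

### Fixed mean-age loadings and the age draw

`loadings_mode = "fixed_mean_ages"` fits the classical latent growth curve
with loadings fixed at the occasion target ages (0, 2.5, 5, 7.5, 10) while
the data were generated at jittered ages. Two findings from developing
this mode shaped the defaults:

* With a *common* measurement residual variance the model is untenable
  under age jitter: the term (growth rate) × (age jitter) inflates each
  occasion's residual variance by up to $\beta_1^2 \sigma^2_{age} \approx
  20\,\mathrm{cm}^2$ — ten times $\sigma^2_{eh}$ — and the fit collapses
  into a degenerate latent covariance. The mode therefore frees the
  residual variances per occasion (standard LGC practice), which absorbs
  the occasion-specific inflation.
* Even then the growth-rate coefficient is not consistent when a single
  age draw is reused: the empirical cross-occasion covariances of the
  jitter, scaled by $\beta_1^2$, perturb the off-diagonal moments from
  which the slope variance is identified. Refitting the model to the exact
  population moments implied by different age draws (a check the test
  suite performs) shows the pseudo-true growth-rate coefficient shifting
  by more than ten percent of the truth between draws at
  $\sigma_{u1} = 0.2$ — a property of the realised schedule, not a stable
  bias. This is why `individual_ages` is the default and why the
  fixed-loadings mode is documented as draw-sensitive rather than used in
  the headline scenario summaries.

## Second stage and summary statistics

`second_stage()` runs the two outcome regressions — outcome on estimated
birth length (model for $\alpha_1$), and on birth length and growth rate
jointly (model for $\alpha_3$, $\alpha_4$) — by closed-form normal
equations with classical OLS standard errors and Wald 95% intervals
($\pm 1.96\,\mathrm{SE}$). $\alpha_3$ is computed and stored but not
summarised as a headline quantity: with both growth summaries in the
model its interpretation is vulnerable to the reversal paradox.

`run_scenario()` aggregates per method and parameter the mean relative
bias $100 \cdot \overline{(\hat\alpha - \alpha)/\alpha}$ and the empirical
coverage of the 1.96-SE intervals, each with Monte-Carlo standard errors
(binomial for coverage). Replicates in which a method fails to converge
are dropped from that method's summaries and counted (`n_converged`);
failures are essentially absent at the default conditions.

## Numerical choices

* **Fitting algorithm.** The variance parameters enter each individual's
  marginal covariance linearly, so the fitter uses Fisher scoring on
  $(\mathrm{vech}\,\Omega, \sigma^2_{eh})$ alternated with GLS for the
  fixed effects — the IGLS scheme, equivalent to ML for Gaussian models —
  with step-halving whenever a proposal leaves the positive-definite cone
  or decreases the likelihood. Convergence is declared at a relative
  log-likelihood change below $10^{-9}$ (max 500 iterations); moment-based
  starting values from the per-individual OLS summaries put typical fits
  at 3–6 iterations. The per-iteration work is $O(J)$ small dense solves,
  implemented in compiled code; a univariate fit at $J = 1000$ takes
  ~20 ms, which is what makes the bootstrap coverage study (40,000 joint
  refits) feasible. Boundary estimates: an indefinite $\hat\Omega$ is
  projected onto the PSD cone with a warning before being used as an
  inflation target.
* **Calibration conventions.** Inflation centres residuals, uses the
  denominator-$J$ covariance, and re-adds means after transforming; the
  post-condition (sample covariance equals the target) is exact to
  numerical precision and is asserted in the tests.
* **SEM optimisation.** The fixed-loadings likelihood depends on the data
  only through the 6-dimensional sample mean and covariance, so each
  evaluation is $O(1)$ in $J$; `nlminb` with a polishing restart, log-scale
  SDs and a log-Cholesky latent covariance. Standard errors come from the
  numerical Hessian at the optimum (invariant for coordinates shared
  between parameterisations).
* **Percentile intervals** use type-7 empirical quantiles.

## What the simulations do and do not show

The generator reproduces the stylised structure of a growth cohort:
Gaussian linear trajectories, complete balanced follow-up, homoscedastic
measurement error, a single Gaussian outcome. Passing the package's
Monte-Carlo checks therefore demonstrates the *estimator* properties —
attenuation, coupling, shrinkage/inflation trade-offs, joint-model
unbiasedness, bootstrap calibration — under those assumptions. It says
nothing about non-linear growth, missing or unbalanced visits,
non-Gaussian outcomes, or interactions between birth size and growth rate,
all of which are out of scope here.

## Problem sizes used in the shipped checks

The packaged test-suite and the results script run reduced-scale versions
of the full 1000-replicate design, chosen to keep Monte-Carlo SEs on
coverage near or below ~1.3 percentage points while completing in minutes:
300–1000 replicates for scenario summaries (cheap methods at 1000), 300
replicates per grid point for the 14-point coverage sweep, and a
200 × 200 bootstrap coverage study. All comparisons against reference
values are made within three Monte-Carlo standard errors.
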