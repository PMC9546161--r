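---
title: "Selection gradients from log-quadratic fitness models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection gradients from log-quadratic fitness models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selgrad)
```

## The model

Regression-based selection analysis summarizes how fitness depends on
phenotype through two quantities defined as averages over the phenotype
distribution: the directional selection gradient
$\beta = \bar W^{-1} \int \partial W(z)/\partial z \; p(z)\,dz$,
and the quadratic gradient
$\gamma = \bar W^{-1} \int \partial^2 W(z)/\partial z \partial z' \; p(z)\,dz$,
with $\bar W$ the mean absolute fitness. $\beta$ predicts the per-generation
response of the mean phenotype through the breeder's-equation relation
$\Delta \bar z = G\beta$; the diagonal of $\gamma$ distinguishes stabilizing
(negative) from disruptive (positive) selection.

This package works with exponential fitness functions with a quadratic
argument,
$$W(z) = \exp\!\big(a + b'z + \tfrac{1}{2} z' g z\big),$$
the model a generalized linear model with a log link fits naturally. When the
phenotype $z$ is multivariate normal with mean $\mu$ and covariance $\Sigma$,
the gradients have closed forms:
$$\beta = (I - g\Sigma)^{-1}(b + g\mu), \qquad
  \gamma = \beta\beta' + (I - g\Sigma)^{-1} g .$$
For one trait these reduce to $\beta = (b + g\mu)/(1 - g\sigma^2)$ and
$\gamma = \big((b+g\mu)^2 + g(1 - g\sigma^2)\big)/(1-g\sigma^2)^2$, and on a
standardized scale ($\mu = 0$, $\sigma^2 = 1$) simply $\beta = b/(1-g)$.
The same formulas serve unstandardized, variance-standardized and
mean-standardized analyses: the package always interprets $\mu$, $\Sigma$ on
the same scale as $b$, $g$, and `standardize_traits()` records the
center/scale so users can move between scales deliberately rather than
implicitly.

Two companion results are implemented because they carry the main
diagnostics. First, the post-selection phenotype distribution is again
normal, with covariance $\Omega = (\Sigma^{-1} - g)^{-1}$ and mean
$\nu = \mu + \Omega(b + g\mu)$; validity of the whole construction requires
$\Omega$ positive definite (univariate: $g < 1/\sigma^2$), i.e. the fitness
function must not curve upward too sharply relative to the phenotype
distribution. Every conversion in the package checks this condition first
and fails with a dedicated error class rather than returning numbers without
meaning. Second, when $g$ is negative definite the model *is* the Gaussian
fitness function $W(z) \propto \exp(-\tfrac12 (z-\theta)'\omega^{-1}(z-\theta))$
with $\omega = (-g)^{-1}$, $\theta = -g^{-1}b$, for which the classical
results $\beta = -S(\mu - \theta)$, $\gamma = \beta\beta' - S$,
$S = (\omega + \Sigma)^{-1}$ hold; the two routes agree to $10^{-10}$ in the
test suite, which is the strongest internal consistency check the algebra
admits.

### Mean fitness

$\bar W = E[W(z)]$ is computed from the pointwise identity
$\bar W = W(z)\, p_{\mu,\Sigma}(z)/p_{\nu,\Omega}(z)$, which is constant in
$z$; the package evaluates it at $z = \mu$. The tests verify the constancy of
the ratio at several values of $z$ and check $\bar W$ against a $10^6$-draw
Monte Carlo mean, so the identity is exercised, not assumed.

## Uncertainty: the delta method

The coefficients $(b, g)$ are not themselves the gradients once $g \neq 0$,
so their (co)variances — whether sampling variances from one fit or
biological variation among cohorts — must be propagated through the
nonlinear conversion. For one standardized trait the first-order
approximations are
$$\mathrm{Var}[\beta] \approx \frac{\mathrm{Var}[b]}{(1-g)^2}
  + \frac{b^2\,\mathrm{Var}[g]}{(1-g)^4}
  + \frac{2b\,\mathrm{Cov}[b,g]}{(1-g)^3},$$
$$\mathrm{Var}[\gamma] \approx \frac{4b^2\,\mathrm{Var}[b]}{(1-g)^4}
  + \frac{(1+2b^2-g)^2\,\mathrm{Var}[g]}{(1-g)^6}
  + \frac{4b(1+2b^2-g)\,\mathrm{Cov}[b,g]}{(1-g)^5}.$$
The middle term of $\mathrm{Var}[\gamma]$ is read as $(1+2b^2-g)^2$; this is
the reading under which the univariate closed forms agree with the generic
multivariate propagation to $10^{-6}$ relative error, which the test suite
checks on 100 random instances.

The multivariate case uses generic first-order propagation
$J\,\mathrm{Cov}[(b, \mathrm{vech}\,g)]\,J'$ with a central-finite-difference
Jacobian (step $\max(10^{-6}, 10^{-6}|x|)$ per coordinate, halved up to 8
times if a perturbed point violates the $\Omega$ condition). A numeric
Jacobian was chosen deliberately: it is verifiable against both the
univariate closed forms and Monte Carlo propagation, and since the
propagation is exactly linear in the input covariance, no accuracy is lost
relative to an analytic Jacobian beyond the $O(h^2)$ differencing error,
which is far below the first-order approximation error itself. First-order
variances are not guaranteed non-negative under extreme curvature; negative
values trigger a warning and are floored at zero when converted to SDs,
never silently.

One convention matters enough to be fixed package-wide: quadratic covariates
are entered as $z_i^2/2$ ("half-quadratic" convention), so the fitted
coefficient *is* $g_i$ and sampling covariances need no post-hoc rescaling.
Cross-product covariates $z_i z_j$ are not halved. The canonical parameter
order everywhere (coefficients, covariance matrices, reports) is
$(b_1,\dots,b_k,\; g_{11},\dots,g_{kk},\; g_{12}, g_{13}, \dots, g_{k-1,k})$.
`convert_unhalved_covariance()` converts results from the other common
convention (unhalved squares, coefficients doubled afterwards): diagonal-g
variances scale by 4, their covariances with every other parameter by 2.

## Estimation

`fit_log_quadratic_glm()` delegates the maximum-likelihood fit to the
standard iteratively reweighted least squares implementations
(`stats::glm()` for Poisson and log-link binomial, `MASS::glm.nb()` for
negative binomial with ML dispersion) and returns the coefficients plus
their sampling covariance (inverse observed information) in canonical order.
For overdispersed counts only $(\hat b, \hat g)$ enter the gradient
formulas, which apply directly to log-link models with additive
overdispersion. Log-link binomial fits are supported but flagged
experimental: with a log link the fitted probabilities are unbounded above,
and non-convergence is common enough that the result carries an explicit
`converged` flag and the bootstrap treats non-converged refits as failures.

`ols_lande_arnold()` implements the classical least-squares estimator on
relative fitness $w = W/\bar W$ with the same design matrix; by default both
gradients come from the single quadratic regression (matching the simulation
protocol below), with the two-step variant (β from a linear-only fit)
available as an option. `bootstrap_se()` provides case bootstrap over
individuals, recomputing relative fitness and sample moments within each
resample; refits that fail are dropped and counted, and more than 20%
failures is an error rather than a quietly degraded answer.
`numerical_average_gradients()` is the model-free averaging route (average
the analytic slope and curvature of the fitted surface over observed
phenotypes, weighted by predicted fitness); it converges to the closed forms
under normality and serves as an independent cross-check rather than the
primary estimator.

Sample phenotype moments use the unbiased ($n-1$) covariance. By default
`gradients_from_fit()` evaluates gradients at the sample $\hat\mu$,
$\hat\Sigma$ of the fitted traits — the only thing available in a data
analysis.

## The simulation framework

`selection_scenario()`/`simulate_dataset()` generate data under the model
itself: $z \sim N(\mu, \Sigma)$ (standard normal by default) and fitness
Poisson with log-mean $a + b'z + \tfrac12 z'gz$. The default study grid
(`scenario_grid()`) crosses $b \in \{-0.5, -0.4, \dots, 0.5\}$ (the step of
0.1 is a package choice; only the range is prescribed by the study design)
with $g \in \{-1, 0, 0.4\}$ at $n = 200$, $a = 0$ — a deliberately modest
sample size at which standard-error quality is genuinely at stake. Replicate
streams are derived deterministically from (master seed, scenario index,
replicate index), so scenarios are independent, reorderable and exactly
reproducible. Default desk-scale replication is 300 datasets per scenario
with 200 bootstrap resamples where the bootstrap is requested; the original
scale (1000/1000) is a parameter, not a code change. The acceptance study in
this repository runs the full 33-scenario grid at 300 replicates with the
bootstrap disabled, since the properties it checks (bias, delta-SE
calibration, MSE ordering) do not involve bootstrap standard errors.

Within the study, GLM gradients are evaluated at the scenario's *true*
phenotype distribution rather than per-replicate sample moments: the
generating scale is known in a simulation, and the delta-method standard
errors propagate coefficient uncertainty only, so evaluating at estimated
moments would add $\hat\mu, \hat\sigma^2$ noise to the estimator that its
standard error is not meant to cover. With conditional evaluation the mean
delta SE tracks the empirical sampling SD within a few percent across the
$g \in \{-1, 0\}$ grid.

What the generator emulates — and what it does not: phenotypes exactly
normal, fitness exactly Poisson around the true log-quadratic surface, no
missing data, no overdispersion beyond the chosen family, no correlation
between individuals. Passing tests therefore demonstrate correctness of the
estimators under the model, and say nothing about robustness to
mis-specified error structures, non-normal phenotypes, or pedigree
structure in real data.

### A finite-sample caveat the study surfaces

The study reproduces the expected qualitative results: estimates essentially
unbiased away from extreme curvature (small biases do appear at $g = 0.4$
and are reported, not asserted away), delta SEs well calibrated, and the GLM
estimators clearly more efficient whenever the fitness surface is actually
curved (at $b = 0.5, g = 0.4$ the paired γ-MSE difference is about $-0.29$).
At $g = 0$, however, the direct OLS γ estimator attains a slightly *smaller*
MSE than the GLM-derived $\hat\gamma = \hat\beta^2 + Q\hat g$, by roughly
+0.001 to +0.004 growing with $|b|$ (paired MC standard errors ~25% of the
difference). The mechanism is visible in the closed-form variance: the
$(1+2b^2-g)^2/(1-g)^6$ factor amplifies $\mathrm{Var}[\hat g]$ in the
indirect estimator, while OLS estimates γ directly with a small attenuation
and lower variance — and at $g = 0$ both models are correctly specified, so
the GLM has no specification advantage to offset this. The corresponding
acceptance check asserts the strict ordering in every scenario and is
expected to fail at exactly these $g = 0$ cells; the package reports the
paired differences and their Monte Carlo errors so the reader can judge the
magnitude.

## Numerical choices

- Positive definiteness is tested by eigenvalue ratio (smallest
  $> 10^{-12} \times$ largest), matching floating-point practice; the theory
  states only the strict condition.
- Conversions use linear solves (`solve(A, b)`), not explicit inverses; the
  matrix $Q = (I - g\Sigma)^{-1}$ is materialized only as a diagnostic.
- γ is explicitly symmetrized ($(\gamma + \gamma')/2$); the
  pre-symmetrization asymmetry is checked to be at rounding level.
- Univariate inputs run through the same $k=1$ matrix path; the univariate
  closed forms appear only as test oracles, never as a second
  implementation.
- The numerical-averaging estimator subtracts the maximum of $f(z)$ before
  exponentiating, so weights never overflow.
- Monte Carlo oracle checks restrict positive curvature to
  $g\sigma^2 \le 0.45$ (so that $\Sigma^{-1} - 2g$ stays positive definite):
  beyond that the importance weights $e^{f(z)}$ have infinite variance and
  the oracle's own standard errors are untrustworthy. This is a constraint
  on where the *oracle* is valid, not on the package's conversions.

## Problem sizes used by the checks

Desk-scale defaults keep every check reproducible on a laptop: $10^6$-draw
Monte Carlo oracles for the closed forms; 100-instance sweeps for the
delta-method and Gaussian-equivalence identities; the full 33-scenario grid
at 300 replicates (no bootstrap) for the estimator-performance study;
200 replicates of $n = 20000$ for coefficient recovery. Bootstrap behaviour
is exercised at smaller scale (tens to hundreds of resamples) where its
determinism and calibration can be checked quickly.

## Known limitations

- All closed forms assume multivariate normal phenotypes before selection;
  nothing here diagnoses or corrects non-normality.
- Fitness functions with cubic or higher log-polynomial terms are out of
  scope, as are random-effects (mixed-model) fitness analyses; coefficient
  (co)variances estimated elsewhere can still be propagated with
  `propagate_multivariate()`.
- First-order uncertainty propagation degrades near the validity boundary
  $g\sigma^2 \to 1$, where the conversion is strongly nonlinear; the
  Monte Carlo comparison in the tests quantifies this at two scales.
- The log-link binomial family frequently fails to converge on real data;
  results are flagged, and the Poisson/negative-binomial families are the
  supported path for count fitness.
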