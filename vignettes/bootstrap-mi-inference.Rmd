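---
title: "Bootstrap confidence intervals for multiply imputed data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap confidence intervals for multiply imputed data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multiple imputation (MI) fills in missing values $M$ times from a
Bayesian predictive model, analyses each completed dataset with the
analyst's complete-data procedure $(\hat\theta_A, W_A)$, and pools the
results. Rubin's rules give the point estimate
$\bar\theta_M = M^{-1}\sum_m \hat\theta_m$ and the total variance

$$T_M = \bar W_M + \left(1 + \tfrac{1}{M}\right) B_M, \qquad
B_M = \frac{1}{M-1}\sum_m (\hat\theta_m - \bar\theta_M)^2 .$$

$T_M$ is a valid frequentist variance when the imputation model and the
analyst's procedure are *congenial* — embeddable in one Bayesian model —
and that model is correctly specified. When the imputer assumes more
than the analyst (reference-based imputation in trials, imputation
ignoring a subgroup structure the analyst uses), or both models are
misspecified (heteroscedastic or non-normal errors), $T_M$ can be biased
in either direction and interval coverage drifts off the advertised
level. `mibootci` implements the bootstrap/MI combinations that have
been recommended in the missing-data literature and the simulation
machinery to measure their repeated-sampling coverage:

* **`pool_rubin()`** — Rubin's rules with analytical within variances.
* **`mi_boot_rubin()`** — impute, then bootstrap each completed dataset
  to estimate the within-imputation variance; pool with Rubin's rules.
* **`mi_boot_pooled_percentile()`** — impute, bootstrap each completed
  dataset, and take empirical percentiles of the pooled $M \times B$
  estimates.
* **`boot_mi_percentile()`** — bootstrap the *incomplete* data, impute
  each resample $M$ times, and take percentiles of the per-resample
  means $\bar\theta_b$.
* **`von_hippel_inference()`** — same grid, but a one-way ANOVA across
  bootstrap replicates estimates the variance components of
  $\hat\theta_{b,m} = \bar\theta_\infty + c_b + d_{bm}$ and yields a
  $t$-interval with Satterthwaite degrees of freedom.

Impute-first methods inherit the congeniality requirement of Rubin's
variance estimator. Bootstrap-first methods target the
repeated-sampling variance of the MI point estimator directly and need
only a consistent point estimator, which is what makes them attractive
for sensitivity analyses such as jump to reference.

# The variance-component interval

Writing MSB and MSW for the between/within-bootstrap mean squares of
the $B \times M$ grid, the components are estimated by
$\hat\sigma^2_\infty = (\mathrm{MSB} - \mathrm{MSW})/M$ and
$\hat\sigma^2_{btw} = \mathrm{MSW}$, giving

$$\widehat{\mathrm{Var}}(\bar\theta_{BM})
  = \Bigl(1 + \tfrac1B\Bigr)\hat\sigma^2_\infty
    + \frac{\hat\sigma^2_{btw}}{BM}
  = \frac{B+1}{BM}\,\mathrm{MSB} - \frac{\mathrm{MSW}}{M},$$

an identity the test suite asserts on random grids. The Satterthwaite
degrees of freedom are

$$\hat\nu = \frac{\widehat{\mathrm{Var}}(\bar\theta_{BM})^2}
  {\dfrac{\bigl(\tfrac{B+1}{BM}\bigr)^2 \mathrm{MSB}^2}{B-1}
   + \dfrac{\mathrm{MSW}^2}{B M^2 (M-1)}},$$

which collapses to exactly $B - 1$ when $\mathrm{MSW} = 0$.

Three numerical choices were genuinely open and are fixed as follows:

* **Negative component fallback.** The moment estimator
  $(\mathrm{MSB}-\mathrm{MSW})/M$ can be negative; we then set
  $\hat\sigma^2_\infty = 0$ and $\hat\sigma^2_{btw}$ to the total
  sample variance $s^2$ of all $BM$ estimates. For the *degrees of
  freedom* we substitute the fallback-implied mean squares
  ($\mathrm{MSB} = \mathrm{MSW} = s^2$) into $\hat\nu$, so that the
  variance ($s^2/(BM)$, necessarily non-negative) and its df come from
  one consistent set of components rather than mixing raw and fallback
  quantities.
* **Fully degenerate grids** (every estimate equal) make $\hat\nu$ a
  0/0 form; we return its analytic limit $B - 1$.
* **Percentile convention.** All percentile intervals use
  `stats::quantile(type = 7)` (linear interpolation between order
  statistics) at probabilities $\alpha/2$ and $1-\alpha/2$, where
  `alpha` is always the two-sided error rate (0.05 for a 95% interval).
  Quantile-type choices move endpoints by $O(1/B)$; type 7 is R's
  default and is fixed package-wide.

The `mi_boot_pooled_percentile()` interval additionally reports the
pooled grid variance $(MB)^{-1}\sum_{m,b}(\hat\theta_{m,b} -
\bar\theta_{MB})^2$ as a diagnostic. By one-way random-effects
algebra its expectation for large $B$ is the within component plus
$(1 - 1/M)$ times the between component, which is why this interval
systematically under-covers for small $M$ even under congeniality — a
behaviour the acceptance suite reproduces.

# Proper imputation

`impute_mar_normal()` is the standard proper sampler for a single
partially observed Gaussian outcome: with complete rows $(X, y)$ and a
noninformative prior, each imputation draws
$\sigma^2 = \mathrm{RSS}/\chi^2_{n_{obs}-p}$, then
$\beta \mid \sigma^2 \sim N(\hat\beta_{OLS}, \sigma^2 (X'X)^{-1})$, and
fills each missing outcome with $x_i'\beta + N(0, \sigma^2)$. Fresh
parameter draws per imputation make the between-imputation variance
reflect parameter uncertainty, which Rubin's rules require.

`impute_jump_to_reference()` is the single-timepoint concretisation of
reference-based imputation for a two-arm trial: posterior parameters
are drawn from the control-arm regression of outcome on baseline
covariates, and *all* missing outcomes — both arms — are filled from
that control-arm conditional distribution. The method deliberately
breaks congeniality: the imputer assumes unobserved active-arm patients
behave like controls, while the analyst's regression of outcome on
baseline and treatment does not. With every observation in the control
arm the procedure reduces exactly to MAR imputation on that arm (the
test suite checks bitwise equality under a shared seed).

An important consequence, easy to miss: jump to reference changes the
*estimand*. With dropout probability $p$ independent of arm, the
probability limit of the treatment coefficient after J2R imputation is
$(1-p)\,\theta_Z$, because the imputed fraction of the active arm
carries no treatment effect. `scenario_truth()` therefore returns
$(1-p)\,\theta_Z$ for J2R scenarios, and coverage in the simulation
engine is assessed against that value; assessing against $\theta_Z$
itself would conflate estimand shift with interval behaviour.

# What the generators emulate

`trial_scenario()` reproduces a two-arm randomised trial: exactly
`arm_size` patients per arm (fixed-count, not Bernoulli), baseline and
outcome bivariate normal with means $(2,\; 2 + 0.2Z)$, variances 0.4
and covariance 0.2, and the outcome missing completely at random with
probability 0.5. At these defaults one replication carries roughly half
the outcome information of a complete trial, recoverable in part
through the baseline correlation of 0.5.

`anthro_scenario()` generates an anthropometric cohort (sex; age and
height bivariate normal; weight linear in sex, age, height; log insulin
index linear in sex, age, weight) with a switch selecting how the
imputation and analysis models disagree: a subgroup analysis whose
imputation model ignores sex, heteroscedastic errors (error SD doubled
for men) that both models ignore, an analysis-only weight-by-sex
interaction, or log-normal $\exp\{N(0, 1/4^2)\}$ errors. Weight is MCAR
for 60% of observations (men only, in the subgroup scenario). The
non-null parameter magnitudes are not dictated by the scenario
constraints; the defaults were chosen once to resemble young-adult
anthropometry — age $\sim N(25, 2^2)$ years, height $\sim N(177, 7^2)$
cm correlated 0.43 with age, weight residual SD 8 kg, log-insulin
residual SD 0.4, weight effect $\theta = 0.02$ per kg — and every value
is a constructor argument, so other magnitudes (for example, values
matching a particular cohort) can be supplied without touching code.

What the generators do *not* emulate: real datasets have non-Gaussian
and multimodal covariates, missingness that depends on observed (or
unobserved) values, multiple partially observed variables, and
longitudinal dropout. Passing coverage here demonstrates the inference
machinery under the stated Gaussian single-outcome designs, not
robustness to those features; the chained-equations setting and
multi-visit reference-based imputation are explicitly out of scope.

# Simulation design and problem sizes

`run_study()` derives one substream per replication (dataset
generation) and one per replication-method pair from the master seed,
so all methods see identical datasets and reruns reproduce summaries
exactly. Failures inside a replication (for instance a rank-deficient
resample beyond the retry budget) are caught, logged with the
replication seed, and counted in the summary rather than aborting the
study.

The package's own reproduction runs, in `scripts/acceptance.R` and the
acceptance tests, use 1,000 replications of the trial design with
B = 200 bootstrap resamples — enough that coverage estimates carry a
Monte-Carlo SE of 0.69 percentage points (`mc_se(0.95, 1000)`) while a
full run of both imputation mechanisms completes in a few minutes on a
single core. The anthropometric property checks use 5,000 replications
for the bootstrap-free Rubin intervals and 400 replications for the
bootstrap-based methods; two-sided checks against a reference coverage
use bands of three Monte-Carlo SEs, and directional over/under-coverage
claims use a one-sided threshold of two Monte-Carlo SEs, both computed
at the replication counts actually used.
B = 200 is below the 1,000+ usually recommended for percentile
intervals, so percentile endpoints are somewhat noisier than variance
based ones at this scale; empirically the coverage patterns are
unchanged.

# Known limitations

* Single scalar target coefficient; no multivariate pooling or joint
  tests.
* One partially observed variable with fully observed predictors; no
  chained equations.
* Homoscedastic model-based OLS variance only (the robustness studied
  here comes from the bootstrap layer, not sandwich variances).
* The bootstrap resamples rows i.i.d.; clustered or time-series
  resampling schemes are not provided.
* Rubin degrees of freedom use the classical large-sample rule; the
  Barnard-Rubin small-sample adjustment is intentionally not applied,
  so very small $n$ with large missing fractions will look slightly
  anti-conservative relative to software that applies it.
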