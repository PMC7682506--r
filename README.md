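# mibootci

Bootstrap confidence intervals for multiply imputed data.

## The problem

Multiple imputation (MI) with Rubin's rules is the workhorse for
missing data: impute M times, analyse each completed dataset, pool the
estimates with

```
theta_bar = mean(theta_hat_m)
T = W_bar + (1 + 1/M) * B,   B = var(theta_hat_m)
```

Rubin's variance `T` is only guaranteed to be right when the imputation
model and the analyst's procedure are *congenial* (embeddable in a
single Bayesian model) and that model is correct. Common practice
breaks this: reference-based ("jump to reference") imputation in
clinical trials, imputation models that ignore a subgroup structure the
analyst uses, heteroscedastic or non-normal errors. Intervals then
over- or under-cover.

`mibootci` implements the combinations of bootstrap and MI that address
this, for a scalar regression coefficient:

| function | order | interval | valid under uncongeniality? |
|---|---|---|---|
| `pool_rubin()` | MI only | t on Rubin df | no |
| `mi_boot_rubin()` | impute, then bootstrap | t on Rubin df, bootstrap within-variances | no |
| `mi_boot_pooled_percentile()` | impute, then bootstrap | percentiles of the pooled M x B estimates | no (and under-covers for small M) |
| `boot_mi_percentile()` | bootstrap, then impute | percentiles of per-resample means | yes |
| `von_hippel_inference()` | bootstrap, then impute | t with Satterthwaite df from one-way ANOVA variance components | yes |

The bootstrap-then-impute grid `theta_hat[b, m]` (B resamples of the
incomplete data, each imputed M times) is produced by
`boot_mi_estimates()`. The variance-component interval estimates
`sigma2_inf` (sampling variance of the infinite-M estimator) and
`sigma2_btw` (between-imputation variance) from the between/within
bootstrap mean squares,

```
Var(theta_bar_BM) = ((B+1)/(B*M)) * MSB - MSW/M
```

with a non-negativity fallback and Satterthwaite degrees of freedom,
so a large B with M = 2 gives uncongeniality-robust intervals at a
fraction of the cost of percentile methods.

Proper imputation is built in: `impute_mar_normal()` (Bayesian normal
linear regression under MAR, posterior draws of both coefficients and
residual variance) and `impute_jump_to_reference()` (all missing
outcomes, both arms, imputed from the control-arm conditional
distribution).

## Worked example

A two-arm trial (n = 500, 250 per arm), baseline `x` and outcome `y`
bivariate normal, true treatment effect 0.2, and half the outcomes
missing at random. Missing outcomes are imputed by jump to reference —
the imputer assumes dropouts in the active arm behave like controls —
which is uncongenial with the analysis (OLS of `y` on `x` and
treatment `z`):

```r
library(mibootci)

scenario <- trial_scenario(imputation_method = "jump_to_reference")
trial <- generate_trial_dataset(scenario, seed = 2026)

imp <- imputation_spec("y", "x", method = "jump_to_reference",
                       treatment = "z", M = 2)
ana <- analysis_spec("y", c("x", "z"), target = "z")

analyse_incomplete(trial, imp, ana, method = "rubin", M = 10, seed = 1)
#> rubin: estimate 0.10266, 95% CI [-0.0061571, 0.21148]
#>   variance 0.0030104, df 102.74, M = 10, B = NA

analyse_incomplete(trial, imp, ana, method = "boot_mi_vonhippel",
                   M = 2, B = 1000, seed = 1)
#> boot_mi_vonhippel: estimate 0.10037, 95% CI [0.031425, 0.16931]
#>   variance 0.0012316, df 516.49, M = 2, B = 1000
```

Both methods agree on the point estimate (~0.10: under jump to
reference with 50% dropout the estimand is (1 - 0.5) x 0.2, not 0.2 —
the imputed half of the active arm carries no treatment effect). But
Rubin's variance is 2.4 times the bootstrap-based one: under this
uncongenial imputation Rubin's rules overstate the repeated-sampling
variance, and across repeated trials their 95% intervals cover the
estimand ~99.8% of the time while the variance-component intervals
stay near 95% (`run_study()` measures exactly this).

A coverage study in a few lines:

```r
study <- run_study(scenario,
                   list(method_settings("rubin", M = 10),
                        method_settings("boot_mi_vonhippel", M = 2, B = 200)),
                   n_reps = 1000, seed = 42)
study$summary   # coverage_pct, median_ci_width, mc_se_pct per method
```

There is also a thin command-line wrapper (`exec/mibootci`) driven by
YAML configs — see `inst/extdata/analyse_example.yml` and
`inst/extdata/simulate_example.yml` — with modes `analyse` (one
incomplete CSV in, one-row inference report out) and `simulate`
(per-replication and summary CSVs out).

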