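#' Two-arm trial scenario
#'
#' Describes the randomised-trial simulation design: a baseline
#' covariate X and outcome Y drawn from a bivariate normal whose outcome
#' mean is shifted by the treatment effect in the active arm, exact
#' fixed-count randomisation, and outcome values set missing completely
#' at random. The defaults are a 500-patient trial with 250 per arm,
#' `(X, Y) ~ N((2, 2 + 0.2 Z), Sigma)` with variances 0.4 and covariance
#' 0.2, and half the outcomes missing.
#'
#' @param n Total sample size.
#' @param arm_size Patients per arm (`2 * arm_size == n`).
#' @param baseline_mean,outcome_mean_control Means of X and of Y in the
#'   control arm.
#' @param treatment_effect Shift of the outcome mean in the active arm.
#' @param var_x,var_y,cov_xy Covariance parameters; the 2 x 2 matrix
#'   must be positive definite.
#' @param missing_prob MCAR probability that an outcome is missing.
#' @param imputation_method `"mar_normal"` or `"jump_to_reference"`;
#'   selects the default imputation model of [scenario_specs()] and the
#'   coverage truth of [scenario_truth()].
#' @return An object of class `c("trial_scenario", "scenario")`.
#' @export
trial_scenario <- function(n = 500L, arm_size = n %/% 2L,
                           baseline_mean = 2, outcome_mean_control = 2,
                           treatment_effect = 0.2, var_x = 0.4,
                           var_y = 0.4, cov_xy = 0.2, missing_prob = 0.5,
                           imputation_method = c("mar_normal",
                                                 "jump_to_reference")) {
  imputation_method <- match.arg(imputation_method)
  if (2L * arm_size != n) stop("arm sizes must sum to n")
  if (var_x <= 0 || var_y <= 0 || var_x * var_y <= cov_xy^2)
    stop("covariance matrix must be positive definite")
  if (missing_prob < 0 || missing_prob > 1)
    stop("missing_prob must lie in [0, 1]")
  structure(list(n = as.integer(n), arm_size = as.integer(arm_size),
                 baseline_mean = baseline_mean,
                 outcome_mean_control = outcome_mean_control,
                 treatment_effect = treatment_effect, var_x = var_x,
                 var_y = var_y, cov_xy = cov_xy,
                 missing_prob = missing_prob,
                 imputation_method = imputation_method),
            class = c("trial_scenario", "scenario"))
}

#' Generate one trial dataset
#'
#' Exactly `arm_size` rows are assigned `z = 1` and the rest `z = 0`
#' (fixed-count randomisation, not Bernoulli). X is drawn marginally and
#' Y from its conditional normal given X and arm, then made MCAR.
#'
#' @param s A [trial_scenario()].
#' @param seed Optional integer seed.
#' @return A data frame with columns `x`, `y` (NA where missing), `z`.
#' @export
generate_trial_dataset <- function(s, seed = NULL) {
  stopifnot(inherits(s, "trial_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- s$n
  z <- rep(c(0, 1), times = c(n - s$arm_size, s$arm_size))
  x <- stats::rnorm(n, s$baseline_mean, sqrt(s$var_x))
  slope <- s$cov_xy / s$var_x
  resid_sd <- sqrt(s$var_y - s$cov_xy^2 / s$var_x)
  y <- s$outcome_mean_control + s$treatment_effect * z +
    slope * (x - s$baseline_mean) + stats::rnorm(n, 0, resid_sd)
  y[stats::runif(n) < s$missing_prob] <- NA_real_
  data.frame(x = x, y = y, z = z)
}

#' Anthropometric regression scenario
#'
#' Describes the second simulation design: sex is Bernoulli, age and
#' height are bivariate normal shifted by sex, weight is a linear
#' function of sex, age and height plus a sex-scaled error, and log
#' insulin index is a linear function of sex, age and weight plus a
#' sex-scaled error:
#' \deqn{weight = iota_0 + iota_1 sex + iota_2 age + iota_3 height +
#'   eta_{sex}^{lambda} e_W}
#' \deqn{loginsindex = beta_0 + beta_1 sex + beta_2 age + theta weight +
#'   eta_{sex}^{omega} e_L}
#' with `eta_sex = 1` for women (sex = 0) and `eta` for men (sex = 1).
#' The target of every analysis is `theta`, the effect of weight on log
#' insulin index. Weight is made MCAR for `missing_prob` of the
#' observations (men only, in the subgroup scenario).
#'
#' The four scenarios switch how imputation and analysis disagree:
#' \describe{
#'   \item{subgroup}{Null sex effects; weight missing among men only;
#'     the imputation model ignores sex while the analysis is fitted to
#'     men only (uncongenial).}
#'   \item{heteroscedastic}{`eta = 2` doubles both error SDs for men
#'     while both models assume homoscedasticity (misspecified).}
#'   \item{omitted_interaction}{The analysis adds a weight-by-sex
#'     interaction that the imputation model omits (uncongenial); the
#'     generated effect of weight is the same in both sexes.}
#'   \item{non_normal}{Errors are log-normal `exp(N(0, 1/4^2))` while
#'     both models assume normality (misspecified).}
#' }
#'
#' The non-null parameter magnitudes are configurable; the defaults are
#' chosen to resemble adult anthropometry (age in years, height cm,
#' weight kg) and satisfy each scenario's defining constraints: sex
#' effects `alpha1`, `iota[2]`, `beta[2]` are null and `eta = 1` except
#' where a scenario says otherwise.
#'
#' @param scenario One of `"subgroup"`, `"heteroscedastic"`,
#'   `"omitted_interaction"`, `"non_normal"`.
#' @param n Sample size.
#' @param pi P(sex = 1) (men).
#' @param alpha0,alpha1,Sigma Mean vector, sex shift and covariance of
#'   (age, height).
#' @param iota Coefficients (intercept, sex, age, height) of the weight
#'   model.
#' @param beta Coefficients (intercept, sex, age) of the log insulin
#'   model.
#' @param theta True effect of weight on log insulin index.
#' @param eta Error-SD multiplier for men; forced to 2 in the
#'   heteroscedastic scenario and 1 otherwise.
#' @param lambda,omega Exponents applied to `eta_sex` in the weight and
#'   log-insulin equations.
#' @param sd_error_w,sd_error_l Error SDs for the normal error
#'   distribution.
#' @param missing_prob MCAR probability that weight is missing (0.6:
#'   probability 0.4 of being observed).
#' @return An object of class `c("anthro_scenario", "scenario")`.
#' @export
anthro_scenario <- function(scenario = c("subgroup", "heteroscedastic",
                                         "omitted_interaction",
                                         "non_normal"),
                            n = 1000L, pi = 0.5,
                            alpha0 = c(25, 177), alpha1 = c(0, 0),
                            Sigma = matrix(c(4, 6, 6, 49), 2L),
                            iota = c(-60, 0, 0.3, 0.7),
                            beta = c(0.5, 0, 0.01), theta = 0.02,
                            eta = NULL, lambda = 1, omega = 1,
                            sd_error_w = 8, sd_error_l = 0.4,
                            missing_prob = 0.6) {
  scenario <- match.arg(scenario)
  eta <- eta %||% if (scenario == "heteroscedastic") 2 else 1
  if (scenario != "heteroscedastic" && eta != 1)
    stop("eta must be 1 except in the heteroscedastic scenario")
  error_dist <- if (scenario == "non_normal") "lognormal" else "normal"
  stopifnot(length(alpha0) == 2L, length(alpha1) == 2L,
            all(dim(Sigma) == 2L), length(iota) == 4L, length(beta) == 3L)
  if (det(Sigma) <= 0 || Sigma[1, 1] <= 0)
    stop("Sigma must be positive definite")
  if (missing_prob < 0 || missing_prob > 1)
    stop("missing_prob must lie in [0, 1]")
  structure(list(scenario = scenario, n = as.integer(n), pi = pi,
                 alpha0 = alpha0, alpha1 = alpha1, Sigma = Sigma,
                 iota = iota, beta = beta, theta = theta, eta = eta,
                 lambda = lambda, omega = omega,
                 sd_error_w = sd_error_w, sd_error_l = sd_error_l,
                 error_dist = error_dist, missing_prob = missing_prob,
                 missing_subgroup = if (scenario == "subgroup") "sex"),
            class = c("anthro_scenario", "scenario"))
}

#' Generate one anthropometric dataset
#'
#' @param s An [anthro_scenario()].
#' @param seed Optional integer seed.
#' @return A data frame with columns `sex`, `age`, `height`, `weight`
#'   (NA where missing) and `loginsindex`.
#' @export
generate_anthro_dataset <- function(s, seed = NULL) {
  stopifnot(inherits(s, "anthro_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- s$n
  sex <- stats::rbinom(n, 1L, s$pi)
  ah <- matrix(stats::rnorm(2L * n), n, 2L) %*% chol(s$Sigma)
  age <- s$alpha0[1] + s$alpha1[1] * sex + ah[, 1]
  height <- s$alpha0[2] + s$alpha1[2] * sex + ah[, 2]
  draw_err <- function(sd) {
    if (s$error_dist == "lognormal") exp(stats::rnorm(n, 0, 1 / 4))
    else stats::rnorm(n, 0, sd)
  }
  eta_sex <- ifelse(sex == 1, s$eta, 1)
  weight <- s$iota[1] + s$iota[2] * sex + s$iota[3] * age +
    s$iota[4] * height + eta_sex^s$lambda * draw_err(s$sd_error_w)
  loginsindex <- s$beta[1] + s$beta[2] * sex + s$beta[3] * age +
    s$theta * weight + eta_sex^s$omega * draw_err(s$sd_error_l)
  out <- data.frame(sex = sex, age = age, height = height,
                    weight = weight, loginsindex = loginsindex)
  mis <- stats::runif(n) < s$missing_prob
  if (!is.null(s$missing_subgroup))
    mis <- mis & (out[[s$missing_subgroup]] == 1)
  out$weight[mis] <- NA_real_
  out
}

#' Generate a dataset from any scenario
#'
#' @param s A [trial_scenario()] or [anthro_scenario()].
#' @param seed Optional integer seed.
#' @return A data frame with missing values.
#' @export
generate_dataset <- function(s, seed = NULL) {
  if (inherits(s, "trial_scenario")) generate_trial_dataset(s, seed)
  else if (inherits(s, "anthro_scenario")) generate_anthro_dataset(s, seed)
  else stop("unknown scenario class")
}

#' Default imputation and analysis specifications for a scenario
#'
#' For the trial, the analysis is always OLS of `y` on `x` and `z` with
#' target `z`; the imputation model is MAR normal on `x` and `z`, or
#' jump to reference with baseline `x` and treatment `z`. For the
#' anthropometric design the imputation model for weight uses sex, age,
#' height and log insulin index as covariates -- except in the subgroup
#' scenario, where it deliberately ignores sex -- and the analysis
#' regresses log insulin index on weight, age and sex (weight and age
#' only, within men, in the subgroup scenario), with a weight-by-sex
#' interaction added in the omitted-interaction scenario. Target is the
#' weight coefficient.
#'
#' @param s A scenario object.
#' @param M Number of imputations stored in the returned
#'   [imputation_spec()].
#' @return `list(imp =, ana =)`.
#' @export
scenario_specs <- function(s, M = 10L) {
  if (inherits(s, "trial_scenario")) {
    imp <- if (s$imputation_method == "jump_to_reference") {
      imputation_spec("y", "x", method = "jump_to_reference",
                      treatment = "z", M = M)
    } else {
      imputation_spec("y", c("x", "z"), method = "mar_normal", M = M)
    }
    return(list(imp = imp, ana = analysis_spec("y", c("x", "z"),
                                               target = "z")))
  }
  stopifnot(inherits(s, "anthro_scenario"))
  switch(s$scenario,
    subgroup = list(
      imp = imputation_spec("weight", c("age", "height", "loginsindex"),
                            M = M),
      ana = analysis_spec("loginsindex", c("weight", "age"),
                          target = "weight",
                          subgroup = list(column = "sex", value = 1))),
    omitted_interaction = list(
      imp = imputation_spec("weight",
                            c("sex", "age", "height", "loginsindex"),
                            M = M),
      ana = analysis_spec("loginsindex", c("weight", "age", "sex"),
                          target = "weight",
                          interactions = list(c("weight", "sex")))),
    list(
      imp = imputation_spec("weight",
                            c("sex", "age", "height", "loginsindex"),
                            M = M),
      ana = analysis_spec("loginsindex", c("weight", "age", "sex"),
                          target = "weight")))
}

#' True target value a scenario's intervals should cover
#'
#' For the trial under MAR imputation this is the generating treatment
#' effect. Under jump to reference the imputation procedure changes the
#' estimand: missing active-arm outcomes are drawn from the control-arm
#' distribution, so with MCAR dropout at rate `p` the probability limit
#' of the treatment coefficient is `(1 - p)` times the generating
#' effect, and repeated-sampling coverage is assessed against that
#' value. For the anthropometric design it is `theta`, the generated
#' effect of weight (identical in both sexes).
#'
#' @param s A scenario object.
#' @return A number.
#' @export
scenario_truth <- function(s) {
  if (inherits(s, "trial_scenario")) {
    if (s$imputation_method == "jump_to_reference")
      return((1 - s$missing_prob) * s$treatment_effect)
    return(s$treatment_effect)
  }
  stopifnot(inherits(s, "anthro_scenario"))
  s$theta
}

#' Monte-Carlo standard error of an estimated coverage probability
#'
#' `100 * sqrt(nominal (1 - nominal) / n_reps)`, in percentage points:
#' the binomial standard error of a coverage estimate over `n_reps`
#' independent simulation replications when the true coverage equals
#' the nominal level.
#'
#' @param nominal Nominal coverage probability in (0, 1).
#' @param n_reps Number of replications.
#' @return Standard error in percentage points.
#' @examples
#' mc_se(0.95, 1000)  # 0.689
#' @export
mc_se <- function(nominal, n_reps) {
  stopifnot(nominal > 0, nominal < 1, n_reps >= 1)
  100 * sqrt(nominal * (1 - nominal) / n_reps)
}

#' Method settings for a simulation study or analysis run
#'
#' @param method One of `"rubin"`, `"mi_boot_rubin"`,
#'   `"mi_boot_pooled"`, `"boot_mi_percentile"`, `"boot_mi_vonhippel"`.
#' @param M Number of imputations.
#' @param B Number of bootstrap resamples (ignored by `"rubin"`).
#' @param alpha Two-sided nominal error rate.
#' @param label Summary label; defaults to `method/M[/B]`.
#' @param point Point-estimator choice passed to
#'   [mi_boot_pooled_percentile()].
#' @return An object of class `method_settings`.
#' @export
method_settings <- function(method = c("rubin", "mi_boot_rubin",
                                       "mi_boot_pooled",
                                       "boot_mi_percentile",
                                       "boot_mi_vonhippel"),
                            M = 10L, B = NULL, alpha = 0.05,
                            label = NULL, point = "imputation") {
  method <- match.arg(method)
  if (method != "rubin" && is.null(B))
    stop("method '", method, "' needs a bootstrap count B")
  label <- label %||%
    paste(c(method, paste0("M", M), if (!is.null(B)) paste0("B", B)),
          collapse = "/")
  structure(list(method = method, M = as.integer(M),
                 B = if (!is.null(B)) as.integer(B), alpha = alpha,
                 label = label, point = point),
            class = "method_settings")
}

#' Analyse an incomplete dataset by a named method
#'
#' Single entry point tying imputation, analysis and pooling together:
#' imputes `data` according to `imp` and returns the interval produced
#' by the requested method. This is the per-replication work-horse of
#' [run_study()] and the engine behind the command-line interface.
#'
#' @param data An incomplete data frame.
#' @param imp An [imputation_spec()]; its `M` is overridden by `M`.
#' @param ana An [analysis_spec()].
#' @param method Method name as in [method_settings()].
#' @param M,B,alpha Method settings.
#' @param point Passed to [mi_boot_pooled_percentile()].
#' @param seed Optional integer seed.
#' @return A [pooled_inference()].
#' @export
analyse_incomplete <- function(data, imp, ana,
                               method = c("rubin", "mi_boot_rubin",
                                          "mi_boot_pooled",
                                          "boot_mi_percentile",
                                          "boot_mi_vonhippel"),
                               M = imp$M, B = NULL, alpha = 0.05,
                               point = "imputation", seed = NULL) {
  method <- match.arg(method)
  imp$M <- as.integer(M)
  if (!is.null(seed)) set.seed(seed)
  switch(method,
    rubin = {
      completed <- impute_missing(data, imp)
      fits <- lapply(completed, fit_ols, spec = ana)
      out <- pool_rubin(vapply(fits, `[[`, 0, "estimate"),
                        vapply(fits, `[[`, 0, "variance"),
                        alpha = alpha, method = "rubin")
      out
    },
    mi_boot_rubin = mi_boot_rubin(data, imp, ana, B = B, alpha = alpha),
    mi_boot_pooled = mi_boot_pooled_percentile(data, imp, ana, B = B,
                                               alpha = alpha,
                                               point = point),
    boot_mi_percentile = boot_mi_percentile(
      boot_mi_estimates(data, imp, ana, B = B), alpha = alpha),
    boot_mi_vonhippel = von_hippel_inference(
      boot_mi_estimates(data, imp, ana, B = B), alpha = alpha))
}

#' Run a coverage simulation study
#'
#' Repeats `n_reps` times: generate a dataset from the scenario, impute
#' and analyse it with every configured method, and record estimate,
#' variance, degrees of freedom and confidence limits. Summaries report
#' the percentage of intervals containing the scenario truth, the
#' median interval width and the Monte-Carlo standard error of the
#' coverage estimate.
#'
#' The master seed spawns one substream per replication (used to
#' generate the data) and one per replication-method pair, so every
#' method sees identical simulated datasets and reruns with the same
#' master seed reproduce the summaries exactly. Replication-method
#' failures are caught, logged with their seed, and counted.
#'
#' @param scenario A [trial_scenario()] or [anthro_scenario()].
#' @param methods A list of [method_settings()].
#' @param n_reps Number of simulation replications.
#' @param seed Master seed (integer).
#' @param true_value Value whose coverage is assessed; defaults to
#'   [scenario_truth()].
#' @param verbose Print progress every 100 replications.
#' @return A list of class `simulation_study` with elements
#'   `replications` (one row per replication x method) and `summary`
#'   (one row per method).
#' @export
run_study <- function(scenario, methods, n_reps, seed = 1L,
                      true_value = scenario_truth(scenario),
                      verbose = FALSE) {
  stopifnot(inherits(scenario, "scenario"), n_reps >= 1)
  if (inherits(methods, "method_settings")) methods <- list(methods)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  specs <- lapply(methods, function(ms) scenario_specs(scenario, M = ms$M))
  rows <- vector("list", n_reps * length(methods))
  k <- 0L
  for (i in seq_len(n_reps)) {
    data <- generate_dataset(scenario, seed = rep_seeds[i])
    for (j in seq_along(methods)) {
      ms <- methods[[j]]
      mseed <- as.integer((as.numeric(rep_seeds[i]) + 104729 * j) %%
                            2147483647)
      res <- tryCatch(
        analyse_incomplete(data, specs[[j]]$imp, specs[[j]]$ana,
                           method = ms$method, M = ms$M, B = ms$B,
                           alpha = ms$alpha, point = ms$point,
                           seed = mseed),
        error = function(e) e)
      k <- k + 1L
      rows[[k]] <- if (inherits(res, "error")) {
        data.frame(rep = i, method = ms$label, estimate = NA_real_,
                   variance = NA_real_, df = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   covered = NA, width = NA_real_, seed = rep_seeds[i],
                   error = conditionMessage(res),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(rep = i, method = ms$label, estimate = res$estimate,
                   variance = res$variance, df = res$df,
                   ci_lower = res$ci_lower, ci_upper = res$ci_upper,
                   covered = res$ci_lower <= true_value &
                     true_value <= res$ci_upper,
                   width = res$ci_upper - res$ci_lower,
                   seed = rep_seeds[i], error = NA_character_,
                   stringsAsFactors = FALSE)
      }
    }
    if (verbose && i %% 100L == 0L)
      message("replication ", i, "/", n_reps)
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(seq_along(methods), function(j) {
    ms <- methods[[j]]
    sel <- reps$method == ms$label
    d <- reps[sel & !is.na(reps$covered), ]
    data.frame(method = ms$label, M = ms$M,
               B = if (is.null(ms$B)) NA_integer_ else ms$B,
               coverage_pct = 100 * mean(d$covered),
               median_ci_width = stats::median(d$width),
               n_reps = nrow(d),
               mc_se_pct = mc_se(1 - ms$alpha, max(1L, nrow(d))),
               n_failed = sum(reps$method == ms$label &
                                is.na(reps$covered)),
               stringsAsFactors = FALSE)
  }))
  structure(list(replications = reps, summary = summ,
                 true_value = true_value, seed = seed),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf("simulation study: %d replications, truth %.4g\n",
              max(x$replications$rep), x$true_value))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
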