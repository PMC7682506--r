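#' Bootstrap variance of a complete-data estimator
#'
#' Draws B with-replacement row resamples of a *completed* dataset, fits
#' the analysis to each, and returns the sample variance (divisor B - 1)
#' of the B estimates. When the analysis has a subgroup restriction, the
#' resample is drawn from all rows and the restriction applied within
#' each resample, mirroring repeated sampling of the full dataset.
#'
#' If a resample yields a rank-deficient design (or an emptied
#' subgroup), it is redrawn up to `max_retries` times before signalling
#' an error; silently dropping failed resamples would bias the variance.
#'
#' @param data A complete data frame.
#' @param spec An [analysis_spec()].
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Optional integer seed.
#' @param max_retries Redraw budget per resample.
#' @return A single non-negative number.
#' @export
bootstrap_variance <- function(data, spec, B, seed = NULL,
                               max_retries = 10L) {
  stats::var(bootstrap_estimates(data, spec, B, seed = seed,
                                 max_retries = max_retries))
}

#' Bootstrap estimates of a complete-data estimator
#'
#' The raw B resampled estimates underlying [bootstrap_variance()];
#' exposed so percentile-type intervals can reuse them.
#'
#' @inheritParams bootstrap_variance
#' @return A numeric vector of length B.
#' @export
bootstrap_estimates <- function(data, spec, B, seed = NULL,
                                max_retries = 10L) {
  stopifnot(inherits(spec, "analysis_spec"), B >= 2)
  if (!is.null(seed)) set.seed(seed)
  dm <- .datmat(data)
  info <- .design_info(colnames(dm), spec)
  # full design on all rows; subgroup filtering happens per resample
  X <- cbind(1, dm[, info$cols, drop = FALSE])
  if (length(info$inter_a))
    X <- cbind(X, dm[, info$inter_a, drop = FALSE] *
                    dm[, info$inter_b, drop = FALSE])
  y <- dm[, info$out]
  if (anyNA(X) || anyNA(y))
    stop("analysis variables contain missing values; impute first")
  keep <- if (info$sub_col > 0L) {
    as.integer(dm[, info$sub_col] == info$sub_val)
  } else integer()
  as.numeric(boot_ols_cpp(X, y, keep, info$target_pos, as.integer(B),
                          as.integer(max_retries)))
}

#' MI boot Rubin: Rubin's rules with bootstrap within-variances
#'
#' Imputes the incomplete data M times, takes the analysis estimate from
#' each completed dataset, replaces the analytical within-imputation
#' variance by the bootstrap variance over B resamples of that completed
#' dataset, and pools with Rubin's rules. The point estimates are the
#' per-imputation estimates themselves, not bootstrap means.
#'
#' This is Rubin's rules with an alternative complete-data variance
#' estimator, so it shares the validity conditions of [pool_rubin()]:
#' approximately nominal coverage under congeniality and correct
#' specification, no guarantee otherwise.
#'
#' @param data An incomplete data frame.
#' @param imp An [imputation_spec()]; `imp$M` imputations are used
#'   (M >= 2).
#' @param ana An [analysis_spec()].
#' @param B Bootstrap resamples per imputed dataset (>= 2).
#' @param alpha Two-sided nominal error rate.
#' @param seed Optional integer seed covering imputation and
#'   bootstrapping.
#' @param max_retries Redraw budget per bootstrap resample.
#' @return A [pooled_inference()] with method `"mi_boot_rubin"`.
#' @export
mi_boot_rubin <- function(data, imp, ana, B, alpha = 0.05, seed = NULL,
                          max_retries = 10L) {
  stopifnot(imp$M >= 2, B >= 2)
  if (!is.null(seed)) set.seed(seed)
  completed <- impute_missing(data, imp)
  ests <- vapply(completed, function(d) fit_ols(d, ana)$estimate, 0)
  wv <- vapply(completed, function(d)
    bootstrap_variance(d, ana, B, max_retries = max_retries), 0)
  out <- pool_rubin(ests, wv, alpha = alpha, method = "mi_boot_rubin")
  out$B <- as.integer(B)
  out
}

#' MI boot pooled percentile interval
#'
#' Imputes M times, bootstraps each completed dataset B times, and forms
#' the confidence interval from the `alpha/2` and `1 - alpha/2`
#' empirical percentiles of the pooled sample of all M x B bootstrap
#' estimates. The `variance` field carries the pooled sample variance
#' (divisor MB) of the grid -- a diagnostic, not the basis of the
#' interval.
#'
#' Under congeniality the pooled sample approximates a posterior sample
#' for the target, but for small M its variance is biased downwards
#' (the between-imputation component enters with weight 1 - 1/M), so
#' these intervals under-cover even in the congenial case unless M is
#' large.
#'
#' @inheritParams mi_boot_rubin
#' @param imp An [imputation_spec()]; M >= 1 is allowed.
#' @param point `"imputation"` (default) takes the mean of the M
#'   per-imputation estimates; `"grid"` the mean of all M x B bootstrap
#'   estimates.
#' @return A [pooled_inference()] with method `"mi_boot_pooled"` and
#'   `df = Inf`.
#' @export
mi_boot_pooled_percentile <- function(data, imp, ana, B, alpha = 0.05,
                                      point = c("imputation", "grid"),
                                      seed = NULL, max_retries = 10L) {
  point <- match.arg(point)
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  completed <- impute_missing(data, imp)
  grid <- t(vapply(completed, function(d)
    bootstrap_estimates(d, ana, B, max_retries = max_retries),
    numeric(B)))
  grid <- estimate_grid(grid, layout = "imputation_major")
  est <- if (point == "grid") {
    mean(grid)
  } else {
    mean(vapply(completed, function(d) fit_ols(d, ana)$estimate, 0))
  }
  ci <- .pctl(as.vector(grid), alpha)
  pooled_inference(estimate = est, variance = pooled_sample_variance(grid),
                   df = Inf, ci_lower = ci[1], ci_upper = ci[2],
                   alpha = alpha, method = "mi_boot_pooled",
                   M = imp$M, B = as.integer(B))
}

#' Pooled sample variance of an estimate grid
#'
#' The variance of all M x B estimates around their grand mean with
#' divisor MB (not MB - 1). For large B this is unbiased for the sum of
#' the expected within-imputation posterior variance and
#' `(1 - 1/M)` times the between-imputation component, which is why the
#' pooled percentile interval is too short for small M.
#'
#' @param grid An [estimate_grid()] or numeric matrix/vector.
#' @return A non-negative number.
#' @export
pooled_sample_variance <- function(grid) {
  v <- as.vector(grid)
  mean((v - mean(v))^2)
}

# Empirical percentile interval endpoints. Quantile convention fixed
# package-wide: linear interpolation between order statistics
# (stats::quantile type 7).
.pctl <- function(x, alpha) {
  unname(stats::quantile(x, c(alpha / 2, 1 - alpha / 2), type = 7,
                         names = FALSE))
}
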