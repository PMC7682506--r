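#' Pool multiple-imputation results with Rubin's rules
#'
#' Combines M per-imputation point estimates and within-imputation
#' variances into a single inference. The pooled estimate is the mean of
#' the estimates; the total variance is
#' `T_M = W_bar + (1 + 1/M) B_M`, where `W_bar` is the mean within
#' variance and `B_M` the sample variance (divisor M - 1) of the
#' estimates. The confidence interval is `estimate +/- t(1 - alpha/2,
#' df) sqrt(T_M)`.
#'
#' Degrees of freedom default to the classical large-sample rule
#' `df = (M - 1) (1 + W_bar / ((1 + 1/M) B_M))^2`, with `df = Inf`
#' (normal quantile) when `B_M = 0`; `df_method = "normal"` forces the
#' normal quantile. The small-sample (Barnard-Rubin) adjustment is
#' deliberately not applied: the package targets the moderate-to-large
#' samples for which the bootstrap comparisons are meaningful.
#'
#' @param estimates Numeric vector of M >= 2 per-imputation estimates.
#' @param within_vars Numeric vector of M non-negative within-imputation
#'   variances.
#' @param alpha Two-sided nominal error rate (default 0.05 for a 95\%
#'   interval).
#' @param df_method `"rubin"` (default) or `"normal"`.
#' @param method Label stored in the result.
#' @return A [pooled_inference()] object.
#' @examples
#' pool_rubin(c(1, 2, 3), c(0.5, 0.5, 0.5))
#' @export
pool_rubin <- function(estimates, within_vars, alpha = 0.05,
                       df_method = c("rubin", "normal"),
                       method = "rubin") {
  df_method <- match.arg(df_method)
  M <- length(estimates)
  if (M < 2L)
    stop("between-imputation variance undefined: need M >= 2 estimates")
  if (length(within_vars) != M)
    stop("estimates and within_vars must have the same length")
  if (anyNA(estimates) || anyNA(within_vars) || any(within_vars < 0))
    stop("invalid input: within-imputation variances must be >= 0")
  est <- mean(estimates)
  B <- stats::var(estimates)
  W <- mean(within_vars)
  total <- W + (1 + 1 / M) * B
  df <- if (df_method == "normal" || B == 0) {
    Inf
  } else {
    (M - 1) * (1 + W / ((1 + 1 / M) * B))^2
  }
  half <- stats::qt(1 - alpha / 2, df) * sqrt(total)
  pooled_inference(estimate = est, variance = total, df = df,
                   ci_lower = est - half, ci_upper = est + half,
                   alpha = alpha, method = method, M = M)
}

#' Pooled inference container
#'
#' Light container for the result of any of the pooling/interval methods:
#' point estimate, variance, degrees of freedom (`Inf` for normal or
#' percentile intervals), confidence limits, the nominal two-sided error
#' rate and a method label.
#'
#' @param estimate,variance,df,ci_lower,ci_upper,alpha Numeric scalars.
#' @param method Character label.
#' @param M,B Imputation and bootstrap counts (for reporting).
#' @return An object of class `pooled_inference`.
#' @export
pooled_inference <- function(estimate, variance, df = Inf, ci_lower,
                             ci_upper, alpha = 0.05, method = "", M = NA_integer_,
                             B = NA_integer_) {
  stopifnot(variance >= 0, ci_lower <= ci_upper)
  eps <- 1e-8 * max(1, abs(estimate))
  if (estimate < ci_lower - eps || estimate > ci_upper + eps) {
    # percentile intervals can in principle exclude the point estimate
    # only through extreme asymmetry; flag loudly if it ever happens
    warning("point estimate lies outside its confidence interval")
  }
  structure(list(estimate = estimate, variance = variance, df = df,
                 ci_lower = ci_lower, ci_upper = ci_upper, alpha = alpha,
                 method = method, M = M, B = B),
            class = "pooled_inference")
}

#' @export
print.pooled_inference <- function(x, ...) {
  cat(sprintf("%s: estimate %.5g, %g%% CI [%.5g, %.5g]\n",
              x$method, x$estimate, 100 * (1 - x$alpha),
              x$ci_lower, x$ci_upper))
  cat(sprintf("  variance %.5g, df %s, M = %s, B = %s\n",
              x$variance, format(round(x$df, 2)),
              format(x$M), format(x$B)))
  invisible(x)
}

#' @export
as.data.frame.pooled_inference <- function(x, ...) {
  data.frame(method = x$method, M = x$M, B = x$B, estimate = x$estimate,
             variance = x$variance, df = x$df, ci_lower = x$ci_lower,
             ci_upper = x$ci_upper, alpha = x$alpha,
             stringsAsFactors = FALSE)
}
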