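#' Fit the analyst's complete-data OLS procedure
#'
#' Fits an ordinary least-squares regression (with intercept) as
#' described by an [analysis_spec()] to a completed dataset and returns
#' the point estimate of the target coefficient together with its
#' classical homoscedastic model-based sampling variance, using the
#' unbiased residual variance `RSS / (n - p)`.
#'
#' @param data A complete (post-imputation) data frame; the outcome and
#'   all covariates must contain no missing values after the subgroup
#'   restriction.
#' @param spec An [analysis_spec()].
#' @return A list of class `estimate_with_variance` with elements
#'   `estimate` and `variance`.
#' @examples
#' d <- data.frame(x = c(0, 1, 2), y = c(0, 1, 1))
#' fit_ols(d, analysis_spec("y", "x", target = "x"))
#' @export
fit_ols <- function(data, spec) {
  stopifnot(inherits(spec, "analysis_spec"))
  dm <- .datmat(data)
  dd <- .design_data(dm, spec)
  p <- ncol(dd$X)
  if (nrow(dd$X) < p + 1L)
    stop("unusable analysis: only ", nrow(dd$X),
         " rows after subgroup restriction for ", p, " coefficients")
  if (anyNA(dd$X) || anyNA(dd$y))
    stop("analysis variables contain missing values; impute first")
  XtX <- crossprod(dd$X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || rcond(XtX) < 1e-12)
    stop("collinear analysis design: rank-deficient after expansion")
  coef <- backsolve(R, forwardsolve(t(R), crossprod(dd$X, dd$y)))
  rss <- sum((dd$y - dd$X %*% coef)^2)
  n <- nrow(dd$X)
  XtXinv <- chol2inv(R)
  j <- dd$target_pos
  structure(list(estimate = coef[j, 1],
                 variance = max(0, rss / (n - p)) * XtXinv[j, j]),
            class = "estimate_with_variance")
}

# Build the design matrix, response, subgroup restriction and target
# position for an analysis_spec against a data matrix.
.design_data <- function(dm, spec) {
  info <- .design_info(colnames(dm), spec)
  keep <- if (info$sub_col > 0L) {
    which(dm[, info$sub_col] == info$sub_val)
  } else seq_len(nrow(dm))
  if (length(keep) == 0L) stop("empty subgroup: no rows selected")
  d <- dm[keep, , drop = FALSE]
  X <- cbind(1, d[, info$cols, drop = FALSE])
  if (length(info$inter_a))
    X <- cbind(X, d[, info$inter_a, drop = FALSE] *
                    d[, info$inter_b, drop = FALSE])
  colnames(X) <- info$coef_names
  list(X = X, y = d[, info$out], target_pos = info$target_pos, keep = keep)
}

# Map an analysis_spec onto column indices of a data matrix. Returns
# 1-based indices (0 = absent) in the layout the C++ kernels expect.
.design_info <- function(cn, spec) {
  col_of <- function(nm) {
    i <- match(nm, cn)
    if (anyNA(i)) stop("column not found in data: ",
                       paste(nm[is.na(i)], collapse = ", "))
    i
  }
  coef_names <- .coef_names(spec)
  inter <- spec$interactions %||% list()
  list(out = col_of(spec$outcome),
       cols = col_of(spec$covariates),
       inter_a = if (length(inter)) col_of(vapply(inter, `[`, "", 1L)) else integer(),
       inter_b = if (length(inter)) col_of(vapply(inter, `[`, "", 2L)) else integer(),
       target_pos = match(spec$target, coef_names),
       coef_names = coef_names,
       sub_col = if (is.null(spec$subgroup)) 0L else col_of(spec$subgroup$column),
       sub_val = if (is.null(spec$subgroup)) 0 else spec$subgroup$value)
}
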