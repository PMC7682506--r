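#' Imputation specification
#'
#' Describes the single-outcome imputation model: which column is
#' imputed, from which fully observed predictors, by which method, and
#' how many times.
#'
#' Two methods are available. `"mar_normal"` is proper Bayesian normal
#' linear-regression imputation under MAR: the model is fitted to the
#' rows with an observed outcome, and each imputation uses an
#' independent posterior draw of the coefficients and residual variance
#' (noninformative prior), so between-imputation variability reflects
#' parameter uncertainty. `"jump_to_reference"` is reference-based
#' imputation for a two-arm trial with one post-baseline outcome: the
#' posterior is drawn from the control-arm (reference) regression of the
#' outcome on the baseline predictors, and missing outcomes in *both*
#' arms are imputed from that control-arm conditional distribution, so
#' unobserved active-arm outcomes "jump to reference".
#'
#' @param outcome Name of the partially observed column to impute.
#' @param predictors Character vector of fully observed predictor
#'   columns. For `"jump_to_reference"` these are the baseline
#'   predictors and must not include the treatment column.
#' @param method `"mar_normal"` or `"jump_to_reference"`.
#' @param treatment Name of the binary (0 = reference/control) treatment
#'   column; required for `"jump_to_reference"`.
#' @param M Number of imputations (>= 1).
#' @return An object of class `imputation_spec`.
#' @examples
#' imputation_spec("y", c("x", "z"), method = "mar_normal", M = 10)
#' @export
imputation_spec <- function(outcome, predictors,
                            method = c("mar_normal", "jump_to_reference"),
                            treatment = NULL, M = 10L) {
  method <- match.arg(method)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(predictors))
  if (outcome %in% predictors)
    stop("outcome '", outcome, "' must not be among the predictors")
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("M must be an integer >= 1")
  if (method == "jump_to_reference") {
    if (is.null(treatment))
      stop("jump_to_reference requires a treatment column")
    if (treatment %in% predictors)
      stop("treatment column must not be among the baseline predictors")
  }
  structure(list(outcome = outcome, predictors = predictors,
                 method = method, treatment = treatment, M = M),
            class = "imputation_spec")
}

#' Analysis specification
#'
#' Describes the analyst's complete-data procedure: an ordinary
#' least-squares regression with an intercept, from which one target
#' coefficient and its homoscedastic model-based variance are reported.
#' The fit can be restricted to a subgroup (applied after imputation)
#' and can include product interaction terms.
#'
#' @param outcome Response column name.
#' @param covariates Character vector of covariate columns (may be empty
#'   for an intercept-only model).
#' @param target Name of the coefficient of interest: `"(Intercept)"`, a
#'   covariate name, or an interaction written `"a:b"`.
#' @param subgroup Optional subgroup restriction: either a column name
#'   (rows with value 1 are kept) or `list(column =, value =)`.
#' @param interactions Optional list of length-2 character vectors; each
#'   pair `c("a", "b")` adds the product column `a:b` to the design.
#' @return An object of class `analysis_spec`.
#' @examples
#' analysis_spec("y", c("x", "z"), target = "z")
#' analysis_spec("loginsindex", c("weight", "age", "sex"),
#'               target = "weight",
#'               interactions = list(c("weight", "sex")))
#' @export
analysis_spec <- function(outcome, covariates = character(), target,
                          subgroup = NULL, interactions = NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(covariates),
            is.character(target), length(target) == 1L)
  if (!is.null(subgroup)) {
    if (is.character(subgroup)) subgroup <- list(column = subgroup, value = 1)
    if (!is.list(subgroup) || is.null(subgroup$column))
      stop("subgroup must be a column name or list(column =, value =)")
    if (is.null(subgroup$value)) subgroup$value <- 1
  }
  if (!is.null(interactions)) {
    ok <- vapply(interactions, function(p)
      is.character(p) && length(p) == 2L, logical(1))
    if (!all(ok)) stop("interactions must be length-2 character vectors")
  }
  spec <- structure(list(outcome = outcome, covariates = covariates,
                         target = target, subgroup = subgroup,
                         interactions = interactions),
                    class = "analysis_spec")
  # target must name a fitted coefficient
  .coef_names(spec)
  spec
}

# Coefficient names of the fitted design, in design order; errors if the
# target is not among them.
.coef_names <- function(spec) {
  nms <- c("(Intercept)", spec$covariates,
           vapply(spec$interactions %||% list(),
                  function(p) paste(p, collapse = ":"), character(1)))
  if (!spec$target %in% nms)
    stop("target '", spec$target, "' is not among the fitted coefficients (",
         paste(nms, collapse = ", "), ")")
  nms
}

`%||%` <- function(a, b) if (is.null(a)) b else a
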