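#' Prepared phenotype
#'
#' Light wrapper recording a phenotype vector together with its preparation
#' stage (`raw`, `rint`, `residual`, `squared_residual`) and the covariate
#' columns used, so scan outputs can state what was regressed.
#'
#' @param values Numeric vector (may contain `NA` for dropped individuals).
#' @param stage One of `"raw"`, `"rint"`, `"residual"`, `"squared_residual"`.
#' @param covariates Character vector of covariate column names used (or
#'   `character(0)`).
#' @return Object of class `prepared_phenotype`.
#' @export
prepared_phenotype <- function(values, stage = "raw", covariates = character(0)) {
  stage <- match.arg(stage, c("raw", "rint", "residual", "squared_residual"))
  structure(list(values = as.numeric(values), stage = stage,
                 covariates = covariates),
            class = "prepared_phenotype")
}

#' @export
print.prepared_phenotype <- function(x, ...) {
  cat("prepared_phenotype (stage:", x$stage, "), n =", length(x$values),
      "(", sum(is.na(x$values)), "missing )\n")
  invisible(x)
}

phenotype_values <- function(x) {
  if (inherits(x, "prepared_phenotype")) x$values else as.numeric(x)
}

phenotype_stage <- function(x, default = "raw") {
  if (inherits(x, "prepared_phenotype")) x$stage else default
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their Blom-offset rank:
#' Phi^-1((r - 3/8) / (n + 1/4)), with mid-ranks for ties. Non-finite values
#' are excluded from ranking and returned as `NA`. The transform is invariant
#' to any strictly monotone transformation of its input.
#'
#' @param values Numeric vector with at least 2 finite values.
#' @return A [prepared_phenotype()] at stage `"rint"`.
#' @export
rint <- function(values) {
  values <- as.numeric(values)
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("rint requires at least 2 finite values")
  r <- rank(values[ok], ties.method = "average")
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  prepared_phenotype(out, "rint")
}

build_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  if (nrow(X) != n) stop("covariate rows (", nrow(X),
                         ") do not match phenotype length (", n, ")")
  cbind(`(Intercept)` = 1, X)
}

#' Residualize a trait against covariates by ordinary least squares
#'
#' Returns OLS residuals of `trait ~ intercept + covariates`. An intercept is
#' always included, so with no covariates the residuals are the centered
#' trait. Individuals with a missing trait or any missing covariate are
#' dropped listwise (returned as `NA`); the number dropped is recorded in the
#' `n_dropped` attribute.
#'
#' @param trait Numeric vector or [prepared_phenotype()].
#' @param covariates Data frame or matrix of covariate columns, or `NULL`.
#' @return A [prepared_phenotype()] at stage `"residual"`.
#' @export
residualize <- function(trait, covariates = NULL) {
  y <- phenotype_values(trait)
  X <- build_design(covariates, length(y))
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  if (sum(ok) <= ncol(X)) stop("too few complete observations to residualize")
  fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
  out <- rep(NA_real_, length(y))
  out[ok] <- fit$residuals
  res <- prepared_phenotype(out, "residual",
                            setdiff(colnames(X), "(Intercept)"))
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' Squared-residual variance phenotype
#'
#' The phenotype used by the variance stage of the Scale test: the
#' element-wise square of the residual of the rank inverse normal transformed
#' trait after covariate adjustment. A genotype associated with this phenotype
#' is associated with the *variance* of the trait.
#'
#' @param trait Raw trait values.
#' @param covariates Covariate data frame for the residualization (the
#'   variance-stage convention is age, age^2, sex and the first 5 PCs).
#' @return A [prepared_phenotype()] at stage `"squared_residual"`.
#' @export
squared_residual_phenotype <- function(trait, covariates = NULL) {
  r <- residualize(rint(trait), covariates)
  out <- prepared_phenotype(r$values^2, "squared_residual", r$covariates)
  attr(out, "n_dropped") <- attr(r, "n_dropped")
  out
}

#' Aggregate repeated clinical laboratory values for one individual
#'
#' Electronic-health-record labs are repeated and contaminated by acute
#' illness; values more than 3-fold above the upper limit of normal are
#' excluded and the median of the remainder is used as the individual's
#' phenotype. Returns `NA` when no value survives the filter.
#'
#' @param values Numeric vector of one individual's laboratory values.
#' @param upper_limit_normal Upper limit of normal for the assay.
#' @return Median of retained values, or `NA_real_`.
#' @export
aggregate_labs <- function(values, upper_limit_normal) {
  values <- values[is.finite(values)]
  keep <- values <= 3 * upper_limit_normal
  if (!any(keep)) return(NA_real_)
  stats::median(values[keep])
}
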