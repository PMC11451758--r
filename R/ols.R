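# Internal least-squares and logistic helpers shared by the scans and
# interaction models. QR-based, so the normal-equations solve used as an
# independent oracle in the tests follows a genuinely different code path.

ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear or constant columns)")
  }
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  n <- nrow(X); k <- ncol(X)
  df <- n - k
  if (df < 1) stop("fewer observations than parameters")
  sigma2 <- sum(res^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  pivot <- qx$pivot
  unpiv <- order(pivot)
  xtx_inv <- xtx_inv[unpiv, unpiv, drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  list(coef = coef, se = se, df = df, sigma2 = sigma2, residuals = res,
       cov_unscaled = xtx_inv)
}

wald_p_t <- function(beta, se, df) {
  2 * stats::pt(abs(beta / se), df = df, lower.tail = FALSE)
}

wald_p_z <- function(beta, se) {
  2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
}

# Logistic regression via stats::glm.fit (IRLS), with separation and
# convergence flags instead of exceptions.
logistic_fit <- function(X, y, maxit = 100, epsilon = 1e-10,
                         separation_beta = 20) {
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear or constant columns)")
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit))
  )
  coef <- fit$coefficients
  w <- fit$weights
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(cov))
  names(se) <- colnames(X)
  list(coef = coef, se = se,
       converged = isTRUE(fit$converged),
       separation = any(abs(coef) > separation_beta, na.rm = TRUE))
}

# Genomic-control lambda: median association chi-square over its null median.
#' Genomic-control lambda of a set of p-values
#'
#' Median of the implied 1-df chi-squared statistics divided by the null
#' median `qchisq(0.5, 1)`; values near 1 indicate a calibrated scan.
#'
#' @param p Vector of p-values.
#' @return Lambda (numeric scalar).
#' @export
gc_lambda <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}
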