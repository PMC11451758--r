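#' Per-variant association scan
#'
#' For every variant passing the minor-allele-frequency and missingness
#' filters, fits `phenotype ~ intercept + dosage + covariates` by OLS and
#' reports the Wald test on the dosage coefficient (t reference with n - k
#' degrees of freedom). Variants failing a filter are retained in the output
#' with an exclusion `reason` and `NA` statistics, so every input variant is
#' accounted for.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Numeric vector or [prepared_phenotype()], aligned to the
#'   genotype individuals.
#' @param covariates Covariate data frame (or `NULL`). Included in the model
#'   alongside the dosage.
#' @param maf_min Minimum minor allele frequency (default 0.001; candidate-gene
#'   analyses conventionally use 0.10).
#' @param missing_rate_max Maximum per-variant missing-call rate (default 0.1).
#' @param stage Phenotype stage label carried into the output (`"mean"` or
#'   `"variance"`); defaults from the prepared phenotype.
#' @return Data frame with one row per input variant: `variant`, `chrom`,
#'   `pos`, `ref`, `alt`, `af`, `n`, `beta`, `se`, `p`, `stage`, `reason`
#'   (`NA` for tested variants).
#' @export
assoc_scan <- function(genotypes, phenotype, covariates = NULL,
                       maf_min = 0.001, missing_rate_max = 0.1,
                       stage = NULL) {
  y <- phenotype_values(phenotype)
  if (is.null(stage)) {
    stage <- switch(phenotype_stage(phenotype),
                    squared_residual = "variance", "mean")
  }
  n_all <- n_individuals(genotypes)
  if (length(y) != n_all) stop("phenotype length does not match genotype rows")
  X <- build_design(covariates, n_all)
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  if (sum(ok) <= ncol(X) + 1) stop("too few complete observations for the scan")
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  if (stats::var(y) == 0) {
    stop("phenotype is constant after filtering; all fits would be degenerate")
  }
  G <- genotypes$dosages[ok, , drop = FALSE]
  n <- nrow(G)

  miss <- colMeans(is.na(G))
  af <- colMeans(G, na.rm = TRUE) / 2
  maf_v <- pmin(af, 1 - af)
  g_var <- apply(G, 2, stats::var, na.rm = TRUE)

  reason <- rep(NA_character_, ncol(G))
  reason[miss > missing_rate_max] <- "missing_rate"
  reason[is.na(reason) & (!is.finite(g_var) | g_var == 0)] <- "monomorphic"
  reason[is.na(reason) & maf_v < maf_min] <- "low_maf"

  beta <- se <- p <- rep(NA_real_, ncol(G))
  n_used <- rep(NA_integer_, ncol(G))
  test_idx <- which(is.na(reason))

  if (length(test_idx)) {
    qx <- qr(X)
    yr <- qr.resid(qx, y)
    k <- ncol(X) + 1L  # covariates + intercept + dosage
    complete <- test_idx[colSums(is.na(G[, test_idx, drop = FALSE])) == 0]
    partial <- setdiff(test_idx, complete)
    if (length(complete)) {
      Gr <- qr.resid(qx, G[, complete, drop = FALSE])
      gg <- colSums(Gr^2)
      gy <- colSums(Gr * yr)
      b <- gy / gg
      rss <- sum(yr^2) - b^2 * gg
      df <- n - k
      s2 <- rss / df
      sev <- sqrt(s2 / gg)
      beta[complete] <- b
      se[complete] <- sev
      p[complete] <- wald_p_t(b, sev, df)
      n_used[complete] <- n
    }
    for (j in partial) {
      g <- G[, j]
      okj <- !is.na(g)
      Xj <- cbind(X[okj, , drop = FALSE], dosage = g[okj])
      fit <- tryCatch(ols_fit(Xj, y[okj]), error = function(e) NULL)
      if (is.null(fit)) { reason[j] <- "degenerate_fit"; next }
      beta[j] <- fit$coef["dosage"]
      se[j] <- fit$se["dosage"]
      p[j] <- wald_p_t(beta[j], se[j], fit$df)
      n_used[j] <- sum(okj)
    }
  }

  out <- data.frame(
    variant = genotypes$variants$id,
    chrom = genotypes$variants$chrom,
    pos = genotypes$variants$pos,
    ref = genotypes$variants$ref,
    alt = genotypes$variants$alt,
    af = af, n = n_used, beta = beta, se = se, p = p,
    stage = stage, reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' The Scale test: paired mean and variance association scans
#'
#' Runs [assoc_scan()] twice on the same variants with identical filtering:
#' once on the rank inverse normal transformed trait (mean effects) and once
#' on the squared residual of that transform after covariate adjustment
#' (variance effects). A variant associated with the second phenotype but not
#' the first is a variance QTL candidate (see [call_vqtls()]).
#'
#' @param genotypes A [genotype_matrix()].
#' @param trait Raw trait values aligned to the genotype individuals.
#' @param covariates Covariates for the mean-stage association model
#'   (convention: age, age^2, sex, first 10 PCs).
#' @param resid_covariates Covariates used to residualize the transformed
#'   trait before squaring (convention: age, age^2, sex, first 5 PCs).
#'   Defaults to `covariates`.
#' @param covariates_in_variance_scan Re-include the residualization
#'   covariates in the variance-stage association model (default `TRUE`;
#'   harmless since the residual is already orthogonal to them).
#' @param maf_min,missing_rate_max Variant filters shared by both scans.
#' @return List with data frames `mean` and `variance` (see [assoc_scan()]).
#' @export
scale_test <- function(genotypes, trait, covariates = NULL,
                       resid_covariates = covariates,
                       covariates_in_variance_scan = TRUE,
                       maf_min = 0.001, missing_rate_max = 0.1) {
  y_mean <- rint(trait)
  y_var <- squared_residual_phenotype(trait, resid_covariates)
  var_covs <- if (covariates_in_variance_scan) resid_covariates else NULL
  list(
    mean = assoc_scan(genotypes, y_mean, covariates,
                      maf_min = maf_min, missing_rate_max = missing_rate_max,
                      stage = "mean"),
    variance = assoc_scan(genotypes, y_var, var_covs,
                          maf_min = maf_min,
                          missing_rate_max = missing_rate_max,
                          stage = "variance")
  )
}

#' Call variance QTLs from paired scan results
#'
#' A variant is a vQTL when its variance association is genome-wide
#' significant (`var_p < var_threshold`) *without* a significant mean effect
#' (`mean_p > mean_threshold`). Both thresholds default to the conventional
#' genome-wide level 5e-8.
#'
#' @param mean_results,variance_results Data frames from [scale_test()] /
#'   [assoc_scan()] for the same variants.
#' @param var_threshold,mean_threshold Decision thresholds.
#' @return Data frame: `variant`, `mean_p`, `var_p`, `var_beta`, `is_vqtl`,
#'   `var_threshold`, `mean_threshold`.
#' @export
call_vqtls <- function(mean_results, variance_results,
                       var_threshold = 5e-8, mean_threshold = 5e-8) {
  m <- merge(
    mean_results[, c("variant", "p")],
    variance_results[, c("variant", "beta", "p")],
    by = "variant", suffixes = c("_mean", "_var")
  )
  names(m) <- c("variant", "mean_p", "var_beta", "var_p")
  m <- m[match(mean_results$variant, m$variant), ]
  m$is_vqtl <- !is.na(m$var_p) & !is.na(m$mean_p) &
    m$var_p < var_threshold & m$mean_p > mean_threshold
  m$var_threshold <- var_threshold
  m$mean_threshold <- mean_threshold
  rownames(m) <- NULL
  m[, c("variant", "mean_p", "var_p", "var_beta", "is_vqtl",
        "var_threshold", "mean_threshold")]
}

#' Bonferroni significance threshold for a candidate-gene scan
#'
#' @param m Number of variants tested (e.g. variants in the gene with minor
#'   allele frequency above 10%).
#' @return `0.05 / m`.
#' @export
bonferroni_threshold <- function(m) {
  if (m < 1) stop("`m` must be at least 1")
  0.05 / m
}

#' Write association results as a summary-statistics TSV
#'
#' @param results Data frame from [assoc_scan()].
#' @param path Output file path.
#' @param comment Optional header comment lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_assoc <- function(results, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
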