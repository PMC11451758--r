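# Shared fixtures for the test suite: small seeded cohorts and an
# independent normal-equations OLS oracle.

# Brute-force OLS via the normal equations; independent of the QR path used
# by the package.
oracle_ols <- function(X, y) {
  xtx <- crossprod(X)
  xty <- crossprod(X, y)
  beta <- solve(xtx, xty)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(xtx)))
  list(coef = drop(beta), se = se, df = df)
}

# Phased-truth LD from a simulate_ld_pair() result.
phased_ld <- function(lp) {
  hap <- rbind(lp$hap1, lp$hap2)
  counts <- c(sum(hap[, 1] == 1 & hap[, 2] == 1),
              sum(hap[, 1] == 1 & hap[, 2] == 0),
              sum(hap[, 1] == 0 & hap[, 2] == 1),
              sum(hap[, 1] == 0 & hap[, 2] == 0))
  ld_from_haplotypes(counts)
}

# Small cohort with one mean-effect variant, used across scan tests.
small_cohort <- function(n = 5000, seed = 42) {
  gm <- simulate_genotypes(n, c(0.3, 0.2, 0.4, 0.15, 0.25), seed = seed)
  covs <- simulate_covariates(n, n_pcs = 5, seed = seed + 1)
  spec <- trait_spec(beta_mean = c(snp2 = 0.15),
                     covariate_effects = c(age = 0.02, sex = 0.3),
                     base_sd = 1, intercept = 5)
  ph <- simulate_trait(gm, covs, spec, seed = seed + 2)
  list(gm = gm, covs = covs, ph = ph,
       cov_cols = covs[, c("age", "age2", "sex", paste0("PC", 1:5))])
}
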