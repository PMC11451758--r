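test_that("an intercept-only dispersion model reduces to homoscedastic OLS", {
  set.seed(2)
  n <- 1000
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n)
  fit <- fit_dglm(y, data.frame(x = x), NULL)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$mean$coef), unname(coef(ols)), tolerance = 1e-8)
  expect_lt(abs(unname(fit$dispersion$coef[1]) -
                  log(sum(resid(ols)^2) / (n - 2))), 0.01)
  expect_true(fit$converged)
  # dispersion-intercept SE matches the exact chi-square information
  expect_equal(unname(fit$dispersion$se[1]), sqrt(2 / (n - 2)),
               tolerance = 0.02)
})

test_that("fit_dglm recovers a generating log-variance effect", {
  n <- 30000
  gm <- simulate_genotypes(n, 0.3, seed = 71, ids = "v")
  covs <- simulate_covariates(n, n_pcs = 3, seed = 72)
  spec <- trait_spec(beta_mean = c(v = 0.1), gamma_var = c(v = 0.4),
                     covariate_effects = c(age = 0.01), base_sd = 1)
  ph <- simulate_trait(gm, covs, spec, seed = 73)
  des <- cbind(data.frame(dosage = dosage(gm, "v")),
               covs[, c("age", "sex", "PC1")])
  fit <- fit_dglm(ph$trait, des, des)
  b <- fit$dispersion$coef["dosage"]
  s <- fit$dispersion$se["dosage"]
  expect_lt(abs(b - 0.4), 3 * s)
  expect_true(fit$converged)
  # mean effect recovered net of the variance effect
  expect_lt(abs(fit$mean$coef["dosage"] - 0.1), 3 * fit$mean$se["dosage"])
})

test_that("the alternating objective is monotone and both weighting options
           agree in sign", {
  set.seed(3)
  n <- 1500
  g <- rbinom(n, 2, 0.3)
  y <- rnorm(n, 0, exp(0.2 * g / 2))
  fit_ml <- fit_dglm(y, data.frame(g = g), data.frame(g = g),
                     leverage_adjust = FALSE)
  expect_true(all(diff(fit_ml$eql_trace) > -1e-8))
  fit_reml <- fit_dglm(y, data.frame(g = g), data.frame(g = g))
  expect_equal(sign(fit_ml$dispersion$coef["g"]),
               sign(fit_reml$dispersion$coef["g"]))
})

test_that("dispersion Wald direction agrees with the group-variance ratio
           and with the variance-scan sign", {
  agree_ratio <- agree_scan <- logical(0)
  for (s in 1:20) {
    gm <- simulate_genotypes(4000, 0.3, seed = 300 + s, ids = "v")
    gv <- if (s %% 2 == 0) 0.3 else -0.3
    ph <- simulate_trait(gm, NULL, trait_spec(gamma_var = c(v = gv)),
                         seed = 400 + s)
    g <- dosage(gm, "v")
    fit <- fit_dglm(ph$trait, data.frame(g = g), data.frame(g = g))
    ratio <- var(ph$trait[g == 2]) / var(ph$trait[g == 0])
    agree_ratio <- c(agree_ratio,
                     sign(fit$dispersion$coef["g"]) == sign(log(ratio)))
    sq <- squared_residual_phenotype(ph$trait, NULL)
    slope <- coef(lm(sq$values ~ g))[2]
    agree_scan <- c(agree_scan,
                    sign(fit$dispersion$coef["g"]) == sign(slope))
  }
  expect_true(all(agree_ratio))
  expect_gte(mean(agree_scan), 0.95)
})

test_that("dispersion_scan ranks the true variance variant first and applies
           the candidate-gene filter", {
  n <- 8000
  gm <- simulate_genotypes(n, c(0.3, 0.15, 0.22, 0.31, 0.38, 0.45, 0.01),
                           seed = 81)
  ph <- simulate_trait(gm, NULL, trait_spec(gamma_var = c(snp1 = 0.35)),
                       seed = 82)
  res <- dispersion_scan(gm, ph$trait, maf_min = 0.10)
  expect_equal(res$reason[7], "low_maf")
  tested <- res[is.na(res$reason), ]
  expect_equal(nrow(tested), 6)
  expect_equal(res$bonferroni_threshold[1], 0.05 / 6)
  expect_equal(tested$variant[which.min(tested$p_dispersion)], "snp1")
  # all-monomorphic region: empty result with logged reason
  dos <- matrix(0, 100, 1)
  gm0 <- genotype_matrix(dos, data.frame(id = "m", chrom = "1", pos = 1,
                                         ref = "A", alt = "G"),
                         paste0("i", 1:100))
  res0 <- dispersion_scan(gm0, rnorm(100))
  expect_equal(res0$reason, "monomorphic")
  expect_true(all(is.na(res0$p_dispersion)))
})
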