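test_that("assoc_scan recovers a planted mean effect and matches the
           normal-equations oracle", {
  sc <- small_cohort()
  res <- assoc_scan(sc$gm, rint(sc$ph$trait), sc$cov_cols)
  hit <- res[res$variant == "snp2", ]
  expect_lt(hit$p, 1e-6)
  # oracle agreement on every variant
  X0 <- cbind(1, as.matrix(sc$cov_cols))
  y <- rint(sc$ph$trait)$values
  for (v in sc$gm$variants$id) {
    o <- oracle_ols(cbind(X0, g = dosage(sc$gm, v)), y)
    row <- res[res$variant == v, ]
    expect_equal(row$beta, unname(o$coef[length(o$coef)]), tolerance = 1e-8)
    expect_equal(row$se, unname(o$se[length(o$se)]), tolerance = 1e-8)
  }
  # p internally consistent with beta/se under the t reference
  expect_equal(res$p, 2 * pt(abs(res$beta / res$se), df = res$n - ncol(X0) - 1,
                             lower.tail = FALSE), tolerance = 1e-10)
})

test_that("assoc_scan filters variants with reasons and survives missing
           genotypes", {
  gm <- simulate_genotypes(2000, c(0.3, 0.0005, 0.25), seed = 9)
  dos <- gm$dosages
  dos[, 3] <- 0                    # monomorphic
  dos[sample(2000, 500), 1] <- NA  # 25% missing
  gm2 <- genotype_matrix(dos, gm$variants, gm$individual_ids)
  y <- withr::with_seed(10, rnorm(2000))
  res <- assoc_scan(gm2, y, maf_min = 0.001, missing_rate_max = 0.1)
  expect_equal(res$reason, c("missing_rate", "low_maf", "monomorphic"))
  expect_true(all(is.na(res$beta)))
  # moderate missingness: per-variant listwise fit
  dos[, 1] <- gm$dosages[, 1]
  dos[1:100, 1] <- NA
  gm3 <- genotype_matrix(dos, gm$variants, gm$individual_ids)
  res3 <- assoc_scan(gm3, y, maf_min = 0.0001, missing_rate_max = 0.1)
  expect_equal(res3$n[1], 1900)
  expect_false(is.na(res3$beta[1]))
  # constant phenotype is rejected up front
  expect_error(assoc_scan(gm, rep(1, 2000)), ".")
})

test_that("scan results are invariant to individual and variant ordering", {
  sc <- small_cohort(n = 1500, seed = 77)
  res <- assoc_scan(sc$gm, sc$ph$trait, sc$cov_cols)
  perm <- withr::with_seed(1, sample(1500))
  gm_p <- genotype_matrix(sc$gm$dosages[perm, ], sc$gm$variants,
                          sc$gm$individual_ids[perm])
  res_p <- assoc_scan(gm_p, sc$ph$trait[perm], sc$cov_cols[perm, ])
  expect_equal(res_p$beta, res$beta, tolerance = 1e-10)
  vperm <- c(3, 1, 5, 2, 4)
  gm_v <- subset_variants(sc$gm, sc$gm$variants$id[vperm])
  res_v <- assoc_scan(gm_v, sc$ph$trait, sc$cov_cols)
  expect_equal(res_v$beta, res$beta[vperm], tolerance = 1e-12)
})

test_that("the Scale test separates mean and variance signals", {
  n <- 20000
  gm <- simulate_genotypes(n, c(0.3, 0.25), seed = 51)
  covs <- simulate_covariates(n, n_pcs = 5, seed = 52)
  cv <- covs[, c("age", "age2", "sex", paste0("PC", 1:5))]
  # pure mean effect: significant in mean scan, null in variance scan
  phm <- simulate_trait(gm, covs, trait_spec(beta_mean = c(snp1 = 0.15)),
                        seed = 53)
  st <- scale_test(gm, phm$trait, cv)
  expect_lt(st$mean$p[1], 1e-8)
  expect_gt(st$variance$p[1], 1e-4)
  # pure variance effect: converse
  phv <- simulate_trait(gm, covs, trait_spec(gamma_var = c(snp2 = 0.3)),
                        seed = 54)
  st2 <- scale_test(gm, phv$trait, cv)
  expect_lt(st2$variance$p[2], 1e-4)
  expect_gt(st2$mean$p[2], 1e-3)
  # determinism: identical input twice gives bit-identical results
  st3 <- scale_test(gm, phv$trait, cv)
  expect_identical(st2, st3)
})

test_that("vQTL calling applies the variance-without-mean rule exactly", {
  mk <- function(p) data.frame(variant = "v", beta = 0.1, p = p)
  call1 <- call_vqtls(mk(0.5), mk(1e-9))
  expect_true(call1$is_vqtl)
  expect_false(call_vqtls(mk(1e-9), mk(1e-9))$is_vqtl)
  expect_false(call_vqtls(mk(0.5), mk(1e-7))$is_vqtl)
  expect_equal(call1$var_threshold, 5e-8)
})

test_that("Bonferroni threshold is 0.05 over the variant count", {
  expect_equal(bonferroni_threshold(76), 0.05 / 76)
  expect_equal(round(bonferroni_threshold(76), 6), 6.58e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(50), 1e-3)
  expect_error(bonferroni_threshold(0))
})
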