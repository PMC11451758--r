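test_that("interaction_test matches a brute-force least-squares solve and is
           exchange-symmetric", {
  for (s in 1:10) {
    n <- 800
    gm <- simulate_genotypes(n, c(0.3, 0.2), seed = 500 + s,
                             ids = c("u", "v"))
    covs <- simulate_covariates(n, n_pcs = 2, seed = 600 + s)
    ph <- simulate_trait(gm, covs,
                         trait_spec(beta_int = data.frame(v1 = "u", v2 = "v",
                                                          beta = 0.05)),
                         seed = 700 + s)
    cv <- covs[, c("age", "sex", "PC1", "PC2")]
    it <- interaction_test(ph$trait, dosage(gm, "u"), dosage(gm, "v"), cv)
    X <- cbind(1, g1 = dosage(gm, "u"), g2 = dosage(gm, "v"),
               gx = dosage(gm, "u") * dosage(gm, "v"), as.matrix(cv))
    o <- oracle_ols(X, ph$trait)
    expect_equal(it$beta_int, unname(o$coef["gx"]), tolerance = 1e-8)
    expect_equal(it$se, unname(o$se["gx"]), tolerance = 1e-8)
    it_swap <- interaction_test(ph$trait, dosage(gm, "v"), dosage(gm, "u"), cv)
    expect_equal(it_swap$beta_int, it$beta_int, tolerance = 1e-12)
  }
})

test_that("Wald CIs and degenerate designs follow the contract", {
  gm <- simulate_genotypes(1000, c(0.3, 0.2), seed = 41, ids = c("u", "v"))
  y <- withr::with_seed(42, rnorm(1000))
  it <- interaction_test(y, dosage(gm, "u"), dosage(gm, "v"))
  expect_equal(it$ci_low, it$beta_int - 1.96 * it$se, tolerance = 1e-10)
  expect_equal(it$ci_high, it$beta_int + 1.96 * it$se, tolerance = 1e-10)
  # constant g2 makes the product collinear with g1
  expect_error(interaction_test(y, dosage(gm, "u"), rep(1, 1000)),
               "rank deficient")
})

test_that("logistic interaction recovers a known log-odds interaction", {
  gm <- simulate_genotypes(60000, c(0.3, 0.3), seed = 43, ids = c("u", "v"))
  ph <- simulate_binary(gm, NULL, intercept = qlogis(0.05),
                        log_or = c(u = 0.1, v = 0.1),
                        interaction_log_or = data.frame(v1 = "u", v2 = "v",
                                                        beta = 0.31),
                        seed = 44)
  it <- interaction_test(ph$status, dosage(gm, "u"), dosage(gm, "v"),
                         family = "logistic")
  expect_lt(abs(it$beta_int - 0.31), 3 * it$se)
  expect_true(it$converged)
  expect_false(it$separation)
})

test_that("interaction_scan ranks the planted partner first and skips the
           focal variant", {
  n <- 10000
  gm <- simulate_genotypes(n, c(0.3, 0.25, 0.2, 0.35, 0.4, 0.15), seed = 45)
  spec <- trait_spec(beta_int = data.frame(v1 = "snp1", v2 = "snp3",
                                           beta = 0.25))
  ph <- simulate_trait(gm, NULL, spec, seed = 46)
  scan <- interaction_scan(gm, "snp1", ph$trait)
  expect_equal(scan$reason[scan$partner == "snp1"], "self")
  tested <- scan[!is.na(scan$p), ]
  expect_equal(tested$partner[which.min(tested$p)], "snp3")
})

test_that("the joint model disambiguates an LD-driven apparent interaction", {
  n <- 50000
  lp <- simulate_ld_pair(n, 0.3, 0.25, 0.95, seed = 47, ids = c("ga", "gb"))
  gmf <- simulate_genotypes(n, 0.3, seed = 48, ids = "gf")
  gf <- dosage(gmf, "gf")
  ga <- dosage(lp$genotypes, "ga")
  gb <- dosage(lp$genotypes, "gb")
  y <- withr::with_seed(49, 0.1 * gf * gb + rnorm(n))
  # marginally, ga appears to interact with gf (it tags gb)
  marg <- interaction_test(y, gf, ga)
  expect_lt(marg$p, 1e-3)
  # jointly, only the gb product term survives
  jt <- joint_interaction_test(y, gf, ga, gb, labels = c("gf", "ga", "gb"))
  expect_lt(jt$p[jt$partner == "gb"], 1e-4)
  expect_gt(jt$p[jt$partner == "ga"], 0.01)
  # converse: independent loci, only ga interacts
  gmb <- simulate_genotypes(n, 0.25, seed = 50, ids = "gc")
  gc_ <- dosage(gmb, "gc")
  y2 <- withr::with_seed(51, 0.1 * gf * ga + rnorm(n))
  jt2 <- joint_interaction_test(y2, gf, ga, gc_, labels = c("gf", "ga", "gc"))
  expect_lt(jt2$p[jt2$partner == "ga"], 1e-4)
  expect_gt(jt2$p[jt2$partner == "gc"], 0.01)
})

test_that("pathogenic allele counts sum dosages and pool counts >= 2", {
  pac <- pathogenic_allele_count(c(1, 0, 2, 1), c(1, 0, 1, 0))
  expect_equal(pac$count, c(2, 0, 3, 1))
  expect_equal(as.character(pac$group), c("2", "0", "2", "1"))
})

test_that("stratified means reproduce weighted-mean identities", {
  set.seed(52)
  y <- rnorm(500)
  g1 <- rbinom(500, 2, 0.3)
  g2 <- rbinom(500, 2, 0.4)
  sm <- stratified_trait_means(y, g1, g2)
  expect_equal(sum(sm$n * sm$mean) / sum(sm$n), mean(y), tolerance = 1e-10)
  expect_equal(sum(sm$n), 500)
  # single stratum equals overall mean
  s1 <- stratified_trait_means(y, rep(0, 500), rep(0, 500))
  expect_equal(s1$mean, mean(y))
  # no-interaction simulation: interaction contrast within 3 SE of 0
  gm <- simulate_genotypes(20000, c(0.3, 0.3), seed = 53, ids = c("u", "v"))
  ph <- simulate_trait(gm, NULL,
                       trait_spec(beta_mean = c(u = 0.2, v = 0.2)), seed = 54)
  it <- interaction_test(ph$trait, dosage(gm, "u"), dosage(gm, "v"))
  expect_lt(abs(it$beta_int), 3 * it$se)
})

test_that("stratified odds ratios follow the 2x2 formula with continuity
           handling", {
  outcome <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  g1 <- c(rep(1, 100), rep(0, 100))
  or <- stratified_odds_ratios(outcome, g1, rep(0, 200))
  row <- or[or$g1 == 1, ]
  expect_equal(row$or, (30 * 90) / (70 * 10), tolerance = 1e-12)
  lse <- sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90)
  expect_equal(row$ci_low, exp(log(row$or) - 1.96 * lse), tolerance = 1e-10)
  expect_equal(or$or[or$reference], 1)
  # zero cell: continuity corrected and flagged
  oc <- stratified_odds_ratios(c(rep(0, 50), rep(1, 5), rep(0, 45)),
                               c(rep(0, 50), rep(1, 50)), rep(0, 100))
  expect_true(oc$continuity_corrected[oc$g1 == 1])
  # null outcome: ORs near 1
  set.seed(55)
  yb <- rbinom(20000, 1, 0.2)
  g <- rbinom(20000, 2, 0.3)
  orn <- stratified_odds_ratios(yb, g, rbinom(20000, 2, 0.3))
  expect_true(all(abs(log(orn$or[!orn$reference])) < 0.35))
})
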