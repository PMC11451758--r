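test_that("simulated genotypes respect HWE structure and allele frequency", {
  n <- 50000
  for (p in c(0.10, 0.25)) {
    gm <- simulate_genotypes(n, p, seed = 7, ids = "v")
    bound <- 3 * sqrt(p * (1 - p) / (2 * n))
    expect_lt(abs(allele_freq(gm)[["v"]] - p), bound)
  }
  gm <- simulate_genotypes(n, 0.5, seed = 8, ids = "v")
  props <- table(factor(dosage(gm, "v"), levels = 0:2)) / n
  expect_equal(as.numeric(props), c(0.25, 0.5, 0.25), tolerance = 0.03)
  # HWE chi-square non-significant for almost all seeds
  pvals <- vapply(1:30, function(s) {
    g <- dosage(simulate_genotypes(20000, 0.3, seed = s, ids = "v"), "v")
    obs <- tabulate(g + 1, 3)
    p <- mean(g) / 2
    expc <- 20000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stats::pchisq(sum((obs - expc)^2 / expc), df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.97)
})

test_that("degenerate and invalid allele frequencies are handled", {
  gm <- simulate_genotypes(1000, 1e-6, seed = 1, ids = "v")
  expect_true(all(dosage(gm, "v") == 0))
  expect_error(simulate_genotypes(100, 1.2, seed = 1), "maf")
  expect_error(simulate_genotypes(100, 0, seed = 1), "maf")
})

test_that("genotype simulation is deterministic given the seed", {
  g1 <- simulate_genotypes(500, c(0.2, 0.4), seed = 11)
  g2 <- simulate_genotypes(500, c(0.2, 0.4), seed = 11)
  expect_identical(g1$dosages, g2$dosages)
  lp1 <- simulate_ld_pair(500, 0.3, 0.2, 0.5, seed = 12)
  lp2 <- simulate_ld_pair(500, 0.3, 0.2, 0.5, seed = 12)
  expect_identical(lp1$genotypes$dosages, lp2$genotypes$dosages)
})

test_that("LD pairs realize the target D-prime and compose from haplotypes", {
  lp <- simulate_ld_pair(50000, 0.3, 0.2, 0.6, seed = 3)
  expect_true(all(lp$hap1 + lp$hap2 == lp$genotypes$dosages))
  expect_lt(abs(phased_ld(lp)$Dprime - 0.6), 0.05)

  # d_prime = 0: genotype correlation ~ 0
  lp0 <- simulate_ld_pair(50000, 0.3, 0.2, 0, seed = 4)
  r <- cor(lp0$genotypes$dosages[, 1], lp0$genotypes$dosages[, 2])
  expect_lt(abs(r), 0.02)

  # perfect LD at matched frequencies: identical dosages
  lp1 <- simulate_ld_pair(2000, 0.5, 0.5, 1, seed = 5)
  expect_true(all(lp1$genotypes$dosages[, 1] == lp1$genotypes$dosages[, 2]))

  # the sign-dependent Dmax makes every |d_prime| <= 1 feasible; beyond that
  # the implied haplotype frequencies leave [0, 1]
  expect_error(simulate_ld_pair(100, 0.9, 0.1, 1.5, seed = 1), "d_prime")
})

test_that("trait simulation reproduces its generating moments", {
  gm <- simulate_genotypes(50000, c(0.3, 0.2), seed = 21)
  # pure noise
  ph0 <- simulate_trait(gm, NULL, trait_spec(base_sd = 1, intercept = 2),
                        seed = 22)
  expect_equal(mean(ph0$trait), 2, tolerance = 0.02)
  expect_equal(var(ph0$trait), 1, tolerance = 0.03)
  # log-linear variance effect: dosage-2 vs dosage-0 variance ratio ~ e
  ph1 <- simulate_trait(gm, NULL, trait_spec(gamma_var = c(snp1 = 0.5)),
                        seed = 23)
  g <- dosage(gm, "snp1")
  ratio <- var(ph1$trait[g == 2]) / var(ph1$trait[g == 0])
  expect_equal(ratio, exp(1), tolerance = 0.12)
  # unknown variant in the spec errors
  expect_error(
    simulate_trait(gm, NULL, trait_spec(beta_mean = c(nope = 1)), seed = 1),
    "absent"
  )
})

test_that("interaction effect in the generative model is recoverable with
           nominal CI coverage", {
  hits <- vapply(1:60, function(s) {
    gm <- simulate_genotypes(4000, c(0.3, 0.3), seed = 100 + s,
                             ids = c("u", "v"))
    spec <- trait_spec(beta_int = data.frame(v1 = "u", v2 = "v", beta = 0.1))
    ph <- simulate_trait(gm, NULL, spec, seed = 200 + s)
    it <- interaction_test(ph$trait, dosage(gm, "u"), dosage(gm, "v"))
    it$ci_low <= 0.1 && 0.1 <= it$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("binary outcomes match their logistic generative model", {
  gm <- simulate_genotypes(40000, c(0.3, 0.3), seed = 31, ids = c("u", "v"))
  ph <- simulate_binary(gm, NULL, intercept = qlogis(0.05), seed = 32)
  expect_equal(mean(ph$status), 0.05, tolerance = 0.01)

  # super-multiplicative odds under a positive interaction
  phx <- simulate_binary(gm, NULL, intercept = qlogis(0.05),
                         log_or = c(u = 0.2, v = 0.2),
                         interaction_log_or = data.frame(v1 = "u", v2 = "v",
                                                         beta = 0.31),
                         seed = 33)
  or <- stratified_odds_ratios(phx$status, dosage(gm, "u"), dosage(gm, "v"))
  or11 <- or$or[or$g1 == 1 & or$g2 == 1]
  or10 <- or$or[or$g1 == 1 & or$g2 == 0]
  or01 <- or$or[or$g1 == 0 & or$g2 == 1]
  expect_gt(or11, or10 * or01)
})
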