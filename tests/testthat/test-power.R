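test_that("interaction-term variance matches HWE moments in both modes", {
  expect_equal(interaction_term_variance(0.10, 0.10, "adjusted"),
               4 * 0.09 * 0.09)
  # product mode against a Monte-Carlo moment oracle
  v <- interaction_term_variance(0.10, 0.10, "product")
  draws <- withr::with_seed(1, {
    g1 <- rbinom(1e6, 2, 0.10); g2 <- rbinom(1e6, 2, 0.10)
    g1 * g2
  })
  mc <- var(draws)
  mc_se <- sd((draws - mean(draws))^2) / sqrt(1e6)
  expect_lt(abs(v - mc), 3 * mc_se)
  # product variance dominates the adjusted variance
  for (m1 in c(0.05, 0.2, 0.5)) for (m2 in c(0.1, 0.4)) {
    expect_gte(interaction_term_variance(m1, m2, "product"),
               interaction_term_variance(m1, m2, "adjusted"))
  }
  # monomorphic limit
  expect_lt(interaction_term_variance(1e-9, 0.2, "product"), 1e-8)
  expect_error(interaction_term_variance(0.6, 0.1), "maf")
})

test_that("analytic power has the right null size, monotonicity and limits", {
  null_spec <- power_spec(1000, 0.05, 0.2, 0.2, beta_int = 0)
  expect_equal(analytic_power(null_spec)$power, 0.05)
  # strictly increasing in n and |beta_int|
  p_small <- analytic_power(power_spec(1e4, 5e-8, 0.1, 0.1, 0.05))$power
  p_big_n <- analytic_power(power_spec(4e5, 5e-8, 0.1, 0.1, 0.05))$power
  p_big_b <- analytic_power(power_spec(1e4, 5e-8, 0.1, 0.1, 0.5))$power
  expect_gt(p_big_n, p_small)
  expect_gt(p_big_b, p_small)
  # alpha = 1 gives power 1
  expect_equal(analytic_power(power_spec(100, 1, 0.1, 0.1, 0.1))$power, 1)
})

test_that("power curves cover the two biobank-scale operating points and are
           monotone", {
  pc <- power_curve(mafs = c(0.01, 0.10), effects = c(0.05, 0.5),
                    n = 400000, alpha = 5e-8, mode = "product")
  expect_gte(pc$power[pc$maf1 == 0.10 & pc$beta_int == 0.05], 0.80)
  expect_gte(pc$power[pc$maf1 == 0.01 & pc$beta_int == 0.5], 0.80)
  for (m in unique(pc$maf1)) {
    sub <- pc[pc$maf1 == m, ]
    expect_true(all(diff(sub$power[order(abs(sub$beta_int))]) >= 0))
  }
})

test_that("simulated power is size-correct under the null and matches the
           adjusted-mode analytic value at interior power", {
  null_spec <- power_spec(300, 0.05, 0.3, 0.3, beta_int = 0)
  sim <- simulated_power(null_spec, reps = 400, seed = 10)
  bound <- 2.58 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(sim$power - 0.05), bound)
  expect_error(simulated_power(null_spec, reps = 0, seed = 1), "reps")
  # interior-power calibration at a smaller scale than the acceptance run
  spec <- power_spec(2000, 0.05, 0.3, 0.3, beta_int = 0.1043,
                     mode = "adjusted")
  target <- analytic_power(spec)$power
  sim2 <- simulated_power(spec, reps = 300, seed = 11)
  se <- sqrt(target * (1 - target) / 300)
  expect_lt(abs(sim2$power - target), 3 * se)
})
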