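#' Variance of the SNP-SNP interaction term under the null
#'
#' For two independent HWE loci with dosages G ~ Binomial(2, p), so
#' E[G] = 2p and E[G^2] = 2p(1-p) + 4p^2:
#' * mode `"product"`: Var(G1 G2) = E[G1^2] E[G2^2] - (E[G1] E[G2])^2, the
#'   variance of the mean-centered product (not residualized for main
#'   effects);
#' * mode `"adjusted"`: Var(G1) Var(G2) = 4 p1(1-p1) p2(1-p2), the
#'   main-effect-residualized variance that drives the asymptotic
#'   non-centrality of the interaction Wald test when main effects are in the
#'   fitted model.
#'
#' Product-mode variance always dominates the adjusted-mode variance.
#'
#' @param maf1,maf2 Minor allele frequencies, each in (0, 0.5].
#' @param mode `"product"` or `"adjusted"`.
#' @return Variance of the interaction term (dimensionless).
#' @export
interaction_term_variance <- function(maf1, maf2,
                                      mode = c("product", "adjusted")) {
  mode <- match.arg(mode)
  if (any(c(maf1, maf2) <= 0 | c(maf1, maf2) > 0.5)) {
    stop("mafs must lie in (0, 0.5]")
  }
  if (mode == "adjusted") {
    return(4 * maf1 * (1 - maf1) * maf2 * (1 - maf2))
  }
  e1 <- 2 * maf1; e2 <- 2 * maf2
  m2_1 <- 2 * maf1 * (1 - maf1) + 4 * maf1^2
  m2_2 <- 2 * maf2 * (1 - maf2) + 4 * maf2^2
  m2_1 * m2_2 - (e1 * e2)^2
}

#' Specification for an interaction power calculation
#'
#' @param n Sample size.
#' @param alpha Significance level in (0, 1).
#' @param maf1,maf2 Minor allele frequencies in (0, 0.5].
#' @param beta_int Interaction effect in trait-SD units per allele product.
#' @param beta1,beta2 Main effects of the two SNPs in trait-SD units
#'   (enter the simulation oracle; absorbed by the fitted main-effect terms
#'   in the analytic non-centrality).
#' @param trait_sd Trait standard deviation (default 1).
#' @param mode Non-centrality convention, `"product"` or `"adjusted"` (see
#'   [interaction_term_variance()]).
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(n, alpha, maf1, maf2, beta_int,
                       beta1 = 0.01, beta2 = 0.01, trait_sd = 1,
                       mode = c("product", "adjusted")) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (n < 1) stop("n must be at least 1")
  if (trait_sd <= 0) stop("trait_sd must be positive")
  structure(list(n = n, alpha = alpha, maf1 = maf1, maf2 = maf2,
                 beta_int = beta_int, beta1 = beta1, beta2 = beta2,
                 trait_sd = trait_sd, mode = mode),
            class = "power_spec")
}

#' Analytic power of the interaction Wald test
#'
#' Non-central chi-squared calculation: the non-centrality parameter is
#' lambda = n * beta_int^2 * Var(interaction term) / trait_sd^2, and power is
#' the upper-tail probability of the non-central chi-squared distribution
#' (1 df, lambda) beyond the upper-alpha quantile of the central chi-squared
#' with 1 df. With beta_int = 0 the power equals alpha exactly.
#'
#' @param spec A [power_spec()].
#' @return Object of class `power_result`: list with `ncp`, `critical_value`,
#'   `power`, `mode` and the spec.
#' @export
analytic_power <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  v <- interaction_term_variance(spec$maf1, spec$maf2, spec$mode)
  ncp <- spec$n * spec$beta_int^2 * v / spec$trait_sd^2
  crit <- stats::qchisq(spec$alpha, df = 1, lower.tail = FALSE)
  pow <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  structure(list(ncp = ncp, critical_value = crit, power = pow,
                 mode = spec$mode, spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("interaction power (%s mode): ncp = %.3f, power = %.4f at alpha = %g\n",
              x$mode, x$ncp, x$power, x$spec$alpha))
  invisible(x)
}

#' Simulation-based power of the interaction Wald test
#'
#' Monte-Carlo oracle for [analytic_power()]: per replicate, draws the two
#' genotypes independently under HWE, generates the trait from the full
#' interaction model (main effects, interaction, unit-variance-scaled
#' Gaussian noise), fits the 4-parameter regression
#' `y ~ g1 + g2 + g1*g2` and counts Wald rejections of the interaction term
#' at `alpha`.
#'
#' @param spec A [power_spec()].
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return List with `power` (rejection fraction), `ci` (95% binomial Wald
#'   interval), `rejections` and `reps`.
#' @export
simulated_power <- function(spec, reps, seed) {
  stopifnot(inherits(spec, "power_spec"))
  if (reps < 1) stop("`reps` must be at least 1")
  rej <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      g1 <- stats::rbinom(spec$n, 2, spec$maf1)
      g2 <- stats::rbinom(spec$n, 2, spec$maf2)
      y <- spec$beta1 * g1 + spec$beta2 * g2 + spec$beta_int * g1 * g2 +
        stats::rnorm(spec$n, 0, spec$trait_sd)
      X <- cbind(1, g1, g2, g1 * g2)
      fit <- tryCatch(ols_fit(X, y), error = function(e) NULL)
      if (is.null(fit)) return(NA)
      p <- wald_p_t(fit$coef[4], fit$se[4], fit$df)
      p < spec$alpha
    }, logical(1))
  })
  rej <- rej[!is.na(rej)]
  k <- sum(rej); m <- length(rej)
  phat <- k / m
  half <- 1.96 * sqrt(phat * (1 - phat) / m)
  list(power = phat, ci = c(max(0, phat - half), min(1, phat + half)),
       rejections = k, reps = m)
}

#' Analytic power over a grid of MAFs and interaction effects
#'
#' Cartesian-grid evaluation of [analytic_power()]. Power is monotone
#' non-decreasing in |beta_int| and, for a fixed effect, in MAF on (0, 0.5].
#'
#' @param mafs Vector of MAFs applied to both loci.
#' @param effects Vector of interaction effects (trait-SD units).
#' @param n Sample size.
#' @param alpha Significance level.
#' @param mode Non-centrality convention.
#' @param trait_sd Trait standard deviation.
#' @return Data frame: `maf1`, `maf2`, `beta_int`, `n`, `alpha`, `mode`,
#'   `ncp`, `power`.
#' @export
power_curve <- function(mafs, effects, n, alpha,
                        mode = c("product", "adjusted"), trait_sd = 1) {
  mode <- match.arg(mode)
  grid <- expand.grid(maf = mafs, beta_int = effects)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- power_spec(n = n, alpha = alpha, maf1 = grid$maf[i],
                     maf2 = grid$maf[i], beta_int = grid$beta_int[i],
                     trait_sd = trait_sd, mode = mode)
    pr <- analytic_power(sp)
    data.frame(maf1 = grid$maf[i], maf2 = grid$maf[i],
               beta_int = grid$beta_int[i], n = n, alpha = alpha,
               mode = mode, ncp = pr$ncp, power = pr$power,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
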