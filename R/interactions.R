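#' SNP-by-SNP interaction test
#'
#' Fits `phenotype ~ intercept + g1 + g2 + g1*g2 + covariates` (OLS for
#' quantitative traits, maximum-likelihood logistic regression for binary
#' outcomes) and reports the Wald test on the product coefficient, with a 95%
#' Wald confidence interval (beta +/- 1.96 se). For binary outcomes the
#' coefficient is an interaction log odds ratio.
#'
#' @param phenotype Numeric trait or 0/1 outcome vector.
#' @param g1,g2 Dosage vectors aligned to the phenotype (alternate-allele
#'   counts; any numeric score such as a pathogenic allele count also works).
#' @param covariates Covariate data frame or `NULL`.
#' @param family `"linear"` or `"logistic"`.
#' @param focal,partner Variant labels carried into the output.
#' @return One-row data frame: `focal`, `partner`, `n`, `beta_int`, `se`,
#'   `ci_low`, `ci_high`, `p`, `beta_g1`, `beta_g2`, `family`, `converged`,
#'   `separation`.
#' @export
interaction_test <- function(phenotype, g1, g2, covariates = NULL,
                             family = c("linear", "logistic"),
                             focal = "g1", partner = "g2") {
  family <- match.arg(family)
  y <- phenotype_values(phenotype)
  n_all <- length(y)
  if (length(g1) != n_all || length(g2) != n_all) {
    stop("g1 and g2 must have the same length as the phenotype")
  }
  X0 <- build_design(covariates, n_all)
  X <- cbind(X0[, 1, drop = FALSE], g1 = g1, g2 = g2, g1xg2 = g1 * g2,
             X0[, -1, drop = FALSE])
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]

  if (family == "linear") {
    fit <- ols_fit(X, y)
    b <- fit$coef["g1xg2"]; s <- fit$se["g1xg2"]
    p <- wald_p_t(b, s, fit$df)
    conv <- TRUE; sep <- FALSE
    b1 <- fit$coef["g1"]; b2 <- fit$coef["g2"]
  } else {
    fit <- logistic_fit(X, y)
    b <- fit$coef["g1xg2"]; s <- fit$se["g1xg2"]
    p <- wald_p_z(b, s)
    conv <- fit$converged; sep <- fit$separation
    b1 <- fit$coef["g1"]; b2 <- fit$coef["g2"]
  }
  data.frame(
    focal = focal, partner = partner, n = length(y),
    beta_int = unname(b), se = unname(s),
    ci_low = unname(b - 1.96 * s), ci_high = unname(b + 1.96 * s),
    p = unname(p), beta_g1 = unname(b1), beta_g2 = unname(b2),
    family = family, converged = conv, separation = sep,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide interaction scan around a focal variant
#'
#' Runs [interaction_test()] of the focal variant against every other variant
#' passing the filters. The focal variant itself, and variants failing a
#' filter, are reported with an exclusion `reason`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param focal Focal variant id (typically a called vQTL).
#' @param phenotype Trait or outcome vector.
#' @param covariates Covariate data frame or `NULL`.
#' @param family `"linear"` or `"logistic"`.
#' @param maf_min,missing_rate_max Partner-variant filters.
#' @return Data frame with one row per partner variant: interaction columns as
#'   in [interaction_test()] plus `af_partner`, `p_bonferroni` and `reason`.
#'   Sort by `p` for ranking.
#' @export
interaction_scan <- function(genotypes, focal, phenotype, covariates = NULL,
                             family = c("linear", "logistic"),
                             maf_min = 0.001, missing_rate_max = 0.1) {
  family <- match.arg(family)
  if (!focal %in% genotypes$variants$id) stop("unknown focal variant: ", focal)
  gf <- dosage(genotypes, focal)
  ids <- genotypes$variants$id
  af <- allele_freq(genotypes)
  maf_v <- pmin(af, 1 - af)
  miss <- colMeans(is.na(genotypes$dosages))
  g_var <- apply(genotypes$dosages, 2, stats::var, na.rm = TRUE)

  reason <- rep(NA_character_, length(ids))
  reason[ids == focal] <- "self"
  reason[is.na(reason) & miss > missing_rate_max] <- "missing_rate"
  reason[is.na(reason) & maf_v < maf_min] <- "low_maf"
  reason[is.na(reason) & (!is.finite(g_var) | g_var == 0)] <- "monomorphic"

  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    if (!is.na(reason[j])) {
      rows[[j]] <- data.frame(
        focal = focal, partner = ids[j], n = NA_integer_,
        beta_int = NA_real_, se = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, p = NA_real_, beta_g1 = NA_real_,
        beta_g2 = NA_real_, family = family, converged = NA,
        separation = NA, stringsAsFactors = FALSE
      )
      next
    }
    rows[[j]] <- tryCatch(
      interaction_test(phenotype, gf, genotypes$dosages[, j], covariates,
                       family = family, focal = focal, partner = ids[j]),
      error = function(e) {
        reason[j] <<- "degenerate_fit"
        data.frame(focal = focal, partner = ids[j], n = NA_integer_,
                   beta_int = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, beta_g1 = NA_real_,
                   beta_g2 = NA_real_, family = family, converged = NA,
                   separation = NA, stringsAsFactors = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  out$af_partner <- af
  n_tested <- sum(is.na(reason))
  out$p_bonferroni <- pmin(1, out$p * n_tested)
  out$reason <- reason
  rownames(out) <- NULL
  out
}

#' Joint interaction model for disambiguating cis epistasis
#'
#' Fits a single model containing a focal variant, two candidate partners and
#' *both* product terms:
#' `phenotype ~ g_focal + g_a + g_b + g_focal*g_a + g_focal*g_b + covariates`.
#' When an apparent interaction with `g_a` is driven only by linkage
#' disequilibrium with a truly interacting `g_b`, the joint model retains the
#' `g_focal*g_b` term and nulls the `g_focal*g_a` term.
#'
#' @param phenotype Trait or outcome vector.
#' @param g_focal,g_a,g_b Dosage vectors.
#' @param covariates Covariate data frame or `NULL`.
#' @param family `"linear"` or `"logistic"`.
#' @param labels Character vector of length 3 naming focal, a, b.
#' @return Two-row data frame (one row per product term) in the
#'   [interaction_test()] format.
#' @export
joint_interaction_test <- function(phenotype, g_focal, g_a, g_b,
                                   covariates = NULL,
                                   family = c("linear", "logistic"),
                                   labels = c("focal", "a", "b")) {
  family <- match.arg(family)
  y <- phenotype_values(phenotype)
  n_all <- length(y)
  X0 <- build_design(covariates, n_all)
  X <- cbind(X0[, 1, drop = FALSE], gf = g_focal, ga = g_a, gb = g_b,
             gfxga = g_focal * g_a, gfxgb = g_focal * g_b,
             X0[, -1, drop = FALSE])
  ok <- is.finite(y) & apply(is.finite(X), 1, all)
  y <- y[ok]; X <- X[ok, , drop = FALSE]

  if (family == "linear") {
    fit <- ols_fit(X, y)
    get_p <- function(b, s) wald_p_t(b, s, fit$df)
    conv <- TRUE; sep <- FALSE
  } else {
    fit <- logistic_fit(X, y)
    get_p <- wald_p_z
    conv <- fit$converged; sep <- fit$separation
  }
  term <- c("gfxga", "gfxgb")
  partner <- labels[2:3]
  b <- fit$coef[term]; s <- fit$se[term]
  data.frame(
    focal = labels[1], partner = partner, n = length(y),
    beta_int = unname(b), se = unname(s),
    ci_low = unname(b - 1.96 * s), ci_high = unname(b + 1.96 * s),
    p = unname(get_p(b, s)),
    beta_g1 = unname(fit$coef["gf"]),
    beta_g2 = unname(fit$coef[c("ga", "gb")]),
    family = family, converged = conv, separation = sep,
    stringsAsFactors = FALSE
  )
}

#' Pathogenic allele count across two sites in the same gene
#'
#' Element-wise sum of the two dosage vectors (so compound heterozygotes
#' carry two pathogenic alleles), with a grouped version pooling counts of 2
#' or more into group "2" for stratified displays.
#'
#' @param g_v1,g_v2 Dosage vectors at the two pathogenic sites.
#' @return Data frame with columns `count` (raw sum) and `group`
#'   (factor "0", "1", "2" with counts >= 2 pooled).
#' @export
pathogenic_allele_count <- function(g_v1, g_v2) {
  if (length(g_v1) != length(g_v2)) stop("dosage vectors differ in length")
  count <- g_v1 + g_v2
  group <- ifelse(count >= 2, "2", as.character(count))
  data.frame(count = count, group = factor(group, levels = c("0", "1", "2")))
}

#' Per genotype-combination trait means
#'
#' Mean, standard error (sd/sqrt(n)) and 95% Wald interval of the trait in
#' each (g1, g2) genotype combination; combinations with no individuals are
#' omitted. This reproduces the stratified-means display used to visualize an
#' interaction (error bars 1.96*SE, n beside each point).
#'
#' @param trait Numeric trait vector.
#' @param g1,g2 Genotype (or group) vectors.
#' @param labels Length-2 character vector naming the two stratifiers.
#' @return Data frame: `g1`, `g2`, `combination`, `n`, `mean`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
stratified_trait_means <- function(trait, g1, g2, labels = c("g1", "g2")) {
  y <- phenotype_values(trait)
  ok <- is.finite(y) & !is.na(g1) & !is.na(g2)
  y <- y[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  key <- interaction(g1, g2, drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    idx <- key == lv
    parts <- strsplit(lv, "|", fixed = TRUE)[[1]]
    n <- sum(idx)
    m <- mean(y[idx])
    se <- if (n > 1) stats::sd(y[idx]) / sqrt(n) else NA_real_
    data.frame(g1 = parts[1], g2 = parts[2],
               combination = paste0(labels[1], "=", parts[1], " x ",
                                    labels[2], "=", parts[2]),
               n = n, mean = m, se = se,
               ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per genotype-combination odds ratios against a reference combination
#'
#' For each (g1, g2) combination, forms the 2x2 case/control table against
#' the reference combination and reports OR = (a*d)/(b*c) with a Wald CI on
#' the log scale (log-SE = sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is
#' zero, 0.5 is added to all four cells and the row is flagged. The reference
#' combination has OR = 1 exactly.
#'
#' @param outcome 0/1 outcome vector.
#' @param g1,g2 Genotype (or group) vectors.
#' @param reference Length-2 vector giving the reference (g1, g2) combination
#'   (default `c(0, 0)`).
#' @param labels Length-2 character vector naming the two stratifiers.
#' @return Data frame: `g1`, `g2`, `combination`, `n`, `cases`, `controls`,
#'   `or`, `ci_low`, `ci_high`, `p`, `continuity_corrected`, `reference`.
#' @export
stratified_odds_ratios <- function(outcome, g1, g2, reference = c(0, 0),
                                   labels = c("g1", "g2")) {
  y <- phenotype_values(outcome)
  ok <- !is.na(y) & !is.na(g1) & !is.na(g2)
  y <- y[ok]; g1 <- g1[ok]; g2 <- g2[ok]
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1")
  key <- paste(g1, g2, sep = "|")
  ref_key <- paste(reference[1], reference[2], sep = "|")
  if (!ref_key %in% key) stop("reference combination has no individuals")
  ref_cases <- sum(y[key == ref_key] == 1)
  ref_controls <- sum(y[key == ref_key] == 0)
  lv <- unique(key[order(g1, g2)])
  out <- do.call(rbind, lapply(lv, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    idx <- key == k
    a <- sum(y[idx] == 1); b <- sum(y[idx] == 0)
    base <- data.frame(
      g1 = parts[1], g2 = parts[2],
      combination = paste0(labels[1], "=", parts[1], " x ",
                           labels[2], "=", parts[2]),
      n = sum(idx), cases = a, controls = b, stringsAsFactors = FALSE
    )
    if (k == ref_key) {
      base$or <- 1; base$ci_low <- NA_real_; base$ci_high <- NA_real_
      base$p <- NA_real_; base$continuity_corrected <- FALSE
      base$reference <- TRUE
      return(base)
    }
    cc <- any(c(a, b, ref_cases, ref_controls) == 0)
    cells <- c(a, b, ref_cases, ref_controls) + if (cc) 0.5 else 0
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    lse <- sqrt(sum(1 / cells))
    base$or <- or
    base$ci_low <- exp(log(or) - 1.96 * lse)
    base$ci_high <- exp(log(or) + 1.96 * lse)
    base$p <- wald_p_z(log(or), lse)
    base$continuity_corrected <- cc
    base$reference <- FALSE
    base
  }))
  rownames(out) <- NULL
  out
}
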