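#' Simulate unlinked genotypes under Hardy-Weinberg equilibrium
#'
#' Each variant is drawn i.i.d. across individuals with genotype probabilities
#' ((1-p)^2, 2p(1-p), p^2) at alternate-allele frequency p, i.e. dosage ~
#' Binomial(2, p). Variants are mutually independent (no LD); use
#' [simulate_ld_pair()] for a pair with a target D'.
#'
#' @param n Number of individuals (>= 1).
#' @param mafs Numeric vector of alternate-allele frequencies, each in (0, 1).
#' @param seed Integer seed; all randomness in this call flows through it and
#'   the caller's RNG state is left untouched.
#' @param ids Optional variant ids (default `snp1 ... snpm`).
#' @param chrom,pos_start Optional variant placement metadata.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, mafs, seed, ids = NULL,
                               chrom = "1", pos_start = 10000L) {
  if (n < 1) stop("`n` must be at least 1")
  if (any(mafs <= 0 | mafs >= 1)) stop("each maf must lie strictly in (0, 1)")
  m <- length(mafs)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  chrom <- rep_len(chrom, m)
  dos <- withr::with_seed(seed, {
    vapply(mafs, function(p) stats::rbinom(n, 2L, p), numeric(n))
  })
  dos <- matrix(dos, nrow = n, ncol = m)
  variants <- data.frame(
    id = ids, chrom = chrom,
    pos = pos_start + 1000L * (seq_len(m) - 1L),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, paste0("id", seq_len(n)))
}

#' Simulate a phased two-locus pair with a target D'
#'
#' Draws 2n haplotypes from the four-class haplotype distribution implied by
#' allele frequencies `pA`, `pB` and the normalized disequilibrium coefficient
#' `d_prime`; genotypes are the sum of an individual's two independent
#' haplotypes. The phased haplotypes are returned so that EM-based LD
#' estimation can be validated against phased truth.
#'
#' D = d_prime * Dmax, with Dmax = min(pA(1-pB), (1-pA)pB) for D >= 0 and
#' Dmax = min(pA pB, (1-pA)(1-pB)) for D < 0.
#'
#' @param n Number of individuals.
#' @param pA,pB Alternate-allele frequencies of the two loci, in (0, 1).
#' @param d_prime Target D' between -1 and 1.
#' @param seed Integer seed.
#' @param ids Variant ids (length 2).
#' @return List with elements `hap1`, `hap2` (n x 2 binary allele indicator
#'   matrices for the two transmitted haplotypes) and `genotypes`
#'   (a [genotype_matrix()] with `hap1 + hap2` as dosages).
#' @export
simulate_ld_pair <- function(n, pA, pB, d_prime, seed, ids = c("snpA", "snpB")) {
  if (any(c(pA, pB) <= 0 | c(pA, pB) >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  if (abs(d_prime) > 1) stop("`d_prime` must lie in [-1, 1]")
  dmax <- if (d_prime >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  D <- d_prime * dmax
  hf <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
          aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  bad <- which(hf < -1e-12 | hf > 1 + 1e-12)
  if (length(bad)) {
    stop("infeasible (pA, pB, d_prime): haplotype frequency ", names(hf)[bad[1]],
         " = ", signif(hf[bad[1]], 4), " is outside [0, 1]")
  }
  hf <- pmax(hf, 0); hf <- hf / sum(hf)
  # haplotype classes: 1 = AB, 2 = Ab, 3 = aB, 4 = ab
  draw <- withr::with_seed(seed, {
    matrix(sample.int(4L, 2L * n, replace = TRUE, prob = hf), ncol = 2L)
  })
  a_allele <- draw <= 2L              # carries alternate allele at locus A
  b_allele <- draw == 1L | draw == 3L # carries alternate allele at locus B
  hap1 <- cbind(a_allele[, 1], b_allele[, 1]) * 1
  hap2 <- cbind(a_allele[, 2], b_allele[, 2]) * 1
  colnames(hap1) <- colnames(hap2) <- ids
  variants <- data.frame(id = ids, chrom = "1", pos = c(10000L, 20000L),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(hap1 + hap2, variants, paste0("id", seq_len(n)))
  list(hap1 = hap1, hap2 = hap2, genotypes = gm)
}

#' Simulate biobank-style covariates
#'
#' Age ~ Uniform(40, 70), sex ~ Bernoulli(0.5) coded 0/1, principal components
#' ~ iid standard normal. `age2` (age squared) is precomputed so the standard
#' covariate set (age, age^2, sex, PCs) can be selected by name.
#'
#' @param n Number of individuals.
#' @param n_pcs Number of principal-component columns (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `individual_id`, `age`, `age2`, `sex`,
#'   `PC1` ... `PCk`.
#' @export
simulate_covariates <- function(n, n_pcs = 10, seed = 1) {
  withr::with_seed(seed, {
    age <- stats::runif(n, 40, 70)
    sex <- stats::rbinom(n, 1, 0.5)
    pcs <- matrix(stats::rnorm(n * n_pcs), nrow = n)
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    data.frame(individual_id = paste0("id", seq_len(n)),
               age = age, age2 = age^2, sex = sex, pcs,
               stringsAsFactors = FALSE)
  })
}

#' Specification of a simulated quantitative trait
#'
#' Collects per-variant mean effects (trait units per alternate allele),
#' log-linear variance effects (log residual variance per allele), pairwise
#' interaction effects (per allele-product), covariate effects, the baseline
#' residual SD and an intercept.
#'
#' @param beta_mean Named numeric vector of per-allele mean effects.
#' @param gamma_var Named numeric vector of per-allele log-variance effects.
#' @param beta_int Data frame with columns `v1`, `v2`, `beta`: interaction
#'   effects per allele product.
#' @param covariate_effects Named numeric vector of effects of covariate
#'   columns (names must exist in the covariate table at simulation time).
#' @param base_sd Baseline residual standard deviation (> 0).
#' @param intercept Trait intercept.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(beta_mean = NULL, gamma_var = NULL, beta_int = NULL,
                       covariate_effects = NULL, base_sd = 1, intercept = 0) {
  if (base_sd <= 0) stop("`base_sd` must be positive")
  if (!is.null(beta_int)) {
    if (!is.data.frame(beta_int) || !all(c("v1", "v2", "beta") %in% names(beta_int))) {
      stop("`beta_int` must be a data frame with columns v1, v2, beta")
    }
  }
  structure(list(beta_mean = beta_mean, gamma_var = gamma_var,
                 beta_int = beta_int, covariate_effects = covariate_effects,
                 base_sd = base_sd, intercept = intercept),
            class = "trait_spec")
}

check_spec_variants <- function(ids, gm, what) {
  missing_ids <- setdiff(ids, gm$variants$id)
  if (length(missing_ids)) {
    stop("trait spec references ", what, " variant(s) absent from the ",
         "genotype matrix: ", paste(missing_ids, collapse = ", "))
  }
}

spec_linear_predictor <- function(genotypes, covariates, beta_mean, beta_int,
                                  covariate_effects, intercept) {
  n <- n_individuals(genotypes)
  eta <- rep(intercept, n)
  if (length(beta_mean)) {
    check_spec_variants(names(beta_mean), genotypes, "mean-effect")
    for (v in names(beta_mean)) eta <- eta + beta_mean[[v]] * dosage(genotypes, v)
  }
  if (!is.null(beta_int) && nrow(beta_int)) {
    check_spec_variants(unique(c(beta_int$v1, beta_int$v2)), genotypes,
                        "interaction")
    for (k in seq_len(nrow(beta_int))) {
      eta <- eta + beta_int$beta[k] *
        dosage(genotypes, beta_int$v1[k]) * dosage(genotypes, beta_int$v2[k])
    }
  }
  if (length(covariate_effects)) {
    missing_cov <- setdiff(names(covariate_effects), names(covariates))
    if (length(missing_cov)) {
      stop("trait spec references covariate(s) absent from the covariate ",
           "table: ", paste(missing_cov, collapse = ", "))
    }
    for (cv in names(covariate_effects)) {
      eta <- eta + covariate_effects[[cv]] * covariates[[cv]]
    }
  }
  eta
}

#' Simulate a quantitative trait from a genotype matrix and a trait spec
#'
#' `trait_i = intercept + sum_v beta_mean_v g_iv + sum_(u,v) beta_int g_iu g_iv
#' + sum_c covariate_effects_c x_ic + eps_i`, with
#' `eps_i ~ Normal(0, base_sd^2 * exp(sum_v gamma_var_v g_iv))`. The log-linear
#' variance term makes the gamma/log-link dispersion submodel of [fit_dglm()]
#' correctly specified, so generating parameters are recoverable.
#'
#' @param genotypes A [genotype_matrix()].
#' @param covariates Covariate data frame (see [simulate_covariates()]);
#'   `NULL` for none.
#' @param spec A [trait_spec()].
#' @param seed Integer seed.
#' @param name Trait column name in the returned table.
#' @return Phenotype data frame: the covariate table (or `individual_id` only)
#'   with the trait appended.
#' @export
simulate_trait <- function(genotypes, covariates = NULL, spec, seed,
                           name = "trait") {
  stopifnot(inherits(spec, "trait_spec"))
  n <- n_individuals(genotypes)
  if (is.null(covariates)) {
    covariates <- data.frame(individual_id = genotypes$individual_ids,
                             stringsAsFactors = FALSE)
  }
  eta <- spec_linear_predictor(genotypes, covariates, spec$beta_mean,
                               spec$beta_int, spec$covariate_effects,
                               spec$intercept)
  log_var <- rep(0, n)
  if (length(spec$gamma_var)) {
    check_spec_variants(names(spec$gamma_var), genotypes, "variance-effect")
    for (v in names(spec$gamma_var)) {
      log_var <- log_var + spec$gamma_var[[v]] * dosage(genotypes, v)
    }
  }
  sds <- spec$base_sd * exp(log_var / 2)
  out <- covariates
  out[[name]] <- eta + withr::with_seed(seed, stats::rnorm(n, 0, sds))
  out
}

#' Simulate a binary outcome from a logistic model
#'
#' `outcome_i ~ Bernoulli(expit(intercept + sum_v log_or_v g_iv +
#' sum_(u,v) interaction_log_or g_iu g_iv + sum_c covariate effects))`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param covariates Covariate data frame or `NULL`.
#' @param intercept Log-odds intercept (e.g. `qlogis(prevalence)` under the
#'   null).
#' @param log_or Named numeric vector of per-allele log odds ratios.
#' @param interaction_log_or Data frame `v1`, `v2`, `beta` of interaction
#'   log odds ratios per allele product.
#' @param covariate_effects Named numeric vector of covariate log-odds effects.
#' @param seed Integer seed.
#' @param name Outcome column name.
#' @return Phenotype data frame with the 0/1 outcome appended.
#' @export
simulate_binary <- function(genotypes, covariates = NULL, intercept,
                            log_or = NULL, interaction_log_or = NULL,
                            covariate_effects = NULL, seed, name = "status") {
  n <- n_individuals(genotypes)
  if (is.null(covariates)) {
    covariates <- data.frame(individual_id = genotypes$individual_ids,
                             stringsAsFactors = FALSE)
  }
  eta <- spec_linear_predictor(genotypes, covariates, log_or,
                               interaction_log_or, covariate_effects,
                               intercept)
  out <- covariates
  out[[name]] <- withr::with_seed(seed, stats::rbinom(n, 1, stats::plogis(eta)))
  out
}
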