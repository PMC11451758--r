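#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Input is
#' either a simulation block (`simulate`) or file paths to genotypes and
#' phenotypes; the remaining fields set covariate conventions, thresholds and
#' optional stages.
#'
#' @param seed Integer master seed; every random stage derives from it.
#' @param outdir Output directory (created if absent).
#' @param simulate `NULL`, or a list with `n`, `mafs` (named vector: variant
#'   id -> alternate allele frequency), optional `chrom` (per-variant),
#'   `n_pcs`, `trait_spec` (a [trait_spec()]) and optional `binary` (list
#'   `intercept`, `log_or`, `interaction_log_or`).
#' @param genotype_file,genotype_format,phenotype_file Alternative file-based
#'   input (`genotype_format` is `"vcf"` or `"dosage_tsv"`).
#' @param trait Trait column name (default `"trait"`).
#' @param covariates_mean Covariate column names for the mean-stage
#'   association model (default age, age^2, sex, first 10 PCs).
#' @param covariates_var Covariate column names for the variance-phenotype
#'   residualization (default age, age^2, sex, first 5 PCs).
#' @param var_threshold,mean_threshold vQTL decision thresholds (default
#'   5e-8 each).
#' @param maf_min,missing_rate_max Genome-wide scan filters (defaults 0.001
#'   and 0.1).
#' @param candidate_regions `NULL` or data frame `chrom`, `start`, `end`
#'   (1-based inclusive) for candidate-gene dispersion scans (MAF filter
#'   0.10).
#' @param focal_variants `NULL` (use called vQTLs) or explicit variant ids
#'   for the interaction scans.
#' @param interaction_maf_min Partner-variant MAF filter (default 0.001).
#' @param power `NULL` or a list `mafs`, `effects`, `n`, `alpha`, `mode` for
#'   the analytic power report.
#' @param write_genotype_files Also write the simulated genotypes to the
#'   output directory (default `FALSE`; they can be large).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir,
                            simulate = NULL,
                            genotype_file = NULL, genotype_format = "vcf",
                            phenotype_file = NULL,
                            trait = "trait",
                            covariates_mean = c("age", "age2", "sex",
                                                paste0("PC", 1:10)),
                            covariates_var = c("age", "age2", "sex",
                                               paste0("PC", 1:5)),
                            var_threshold = 5e-8, mean_threshold = 5e-8,
                            maf_min = 0.001, missing_rate_max = 0.1,
                            candidate_regions = NULL,
                            focal_variants = NULL,
                            interaction_maf_min = 0.001,
                            power = NULL,
                            write_genotype_files = FALSE) {
  for (thr in c(var_threshold, mean_threshold, maf_min, missing_rate_max,
                interaction_maf_min)) {
    if (thr < 0 || thr >= 1) stop("thresholds must lie in [0, 1)")
  }
  if (is.null(simulate) && is.null(genotype_file)) {
    stop("provide either a `simulate` block or a `genotype_file`")
  }
  if (!is.null(candidate_regions)) {
    cr <- as.data.frame(candidate_regions)
    if (!all(c("chrom", "start", "end") %in% names(cr)) ||
        any(cr$start > cr$end)) {
      stop("`candidate_regions` needs chrom/start/end with start <= end")
    }
  }
  if (!is.null(genotype_file) && !file.exists(genotype_file)) {
    stop("genotype file not found: ", genotype_file)
  }
  if (!is.null(phenotype_file) && !file.exists(phenotype_file)) {
    stop("phenotype file not found: ", phenotype_file)
  }
  structure(list(
    seed = as.integer(seed), outdir = outdir, simulate = simulate,
    genotype_file = genotype_file, genotype_format = genotype_format,
    phenotype_file = phenotype_file, trait = trait,
    covariates_mean = covariates_mean, covariates_var = covariates_var,
    var_threshold = var_threshold, mean_threshold = mean_threshold,
    maf_min = maf_min, missing_rate_max = missing_rate_max,
    candidate_regions = candidate_regions, focal_variants = focal_variants,
    interaction_maf_min = interaction_maf_min, power = power,
    write_genotype_files = write_genotype_files
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; a `simulate.trait_spec`
#' block is converted to a [trait_spec()] (its `beta_int` sub-block as a data
#' frame of `v1`, `v2`, `beta`).
#'
#' @param path YAML file path.
#' @param outdir,seed Optional overrides of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(outdir)) raw$outdir <- outdir
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    # YAML 1.1 reads the bare key `n` as a boolean; map it back
    names(sim)[names(sim) %in% c("FALSE", "F", "N")] <- "n"
    sim$mafs <- unlist(sim$mafs)
    if (!is.null(sim$trait_spec)) {
      ts <- sim$trait_spec
      bi <- if (!is.null(ts$beta_int)) {
        do.call(rbind, lapply(ts$beta_int, as.data.frame))
      } else NULL
      sim$trait_spec <- trait_spec(
        beta_mean = unlist(ts$beta_mean), gamma_var = unlist(ts$gamma_var),
        beta_int = bi, covariate_effects = unlist(ts$covariate_effects),
        base_sd = ts$base_sd %||% 1, intercept = ts$intercept %||% 0
      )
    }
    raw$simulate <- sim
  }
  if (!is.null(raw$candidate_regions)) {
    raw$candidate_regions <-
      do.call(rbind, lapply(raw$candidate_regions, as.data.frame))
  }
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash over the serialized config (minus outdir), for
# self-describing output headers; a label, not cryptographic.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  bytes <- utf8ToInt(as.character(jsonlite::serializeJSON(cfg)))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_tsv <- function(df, path, stage, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# stage: ", stage),
               paste0("# config_hash: ", hash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_stop <- function(stage, e) {
  stop(structure(
    class = c("vqtlgxg_pipeline_error", "error", "condition"),
    list(message = paste0("pipeline stage '", stage, "' failed [",
                          "E_", toupper(stage), "]: ", conditionMessage(e)),
         call = NULL, stage = stage)
  ))
}

run_stage <- function(stage, report, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) pipeline_stop(stage, e))
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full vQTL-to-interaction analysis pipeline
#'
#' Executes, in order: cohort input (simulation or file), phenotype
#' preparation, the Scale test (paired mean/variance scans), vQTL calling,
#' candidate-gene dispersion scans, interaction scans around each focal
#' variant, stratified means for the top interaction hit, EM-based LD for the
#' top pair, and an analytic power report. Every stage writes a
#' self-describing TSV (stage name and config hash in header comments) under
#' `config$outdir`, and a JSON run report records per-stage counts and
#' wall-clock times. The run is fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage log lines via `message()` (default `TRUE`).
#' @return The run report (list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message("[vqtlgxg] ", ...)
  report <- list(config_hash = hash,
                 package_version = as.character(utils::packageVersion("vqtlgxg")),
                 stages = list(), counts = list())
  base_seed <- config$seed %% (2^28)

  # --- genotypes -----------------------------------------------------------
  st <- run_stage("genotypes", report, {
    if (!is.null(config$genotype_file)) {
      read_genotypes(config$genotype_file, config$genotype_format)
    } else {
      sim <- config$simulate
      simulate_genotypes(sim$n, unname(sim$mafs), seed = base_seed,
                         ids = names(sim$mafs),
                         chrom = sim$chrom %||% "1")
    }
  })
  gm <- st$value
  report$stages$genotypes <- st$elapsed
  report$counts$variants_read <- n_variants(gm)
  report$counts$individuals <- n_individuals(gm)
  say("genotypes: ", n_individuals(gm), " individuals x ",
      n_variants(gm), " variants")
  if (config$write_genotype_files) {
    write_genotypes(gm, file.path(config$outdir, "genotypes.vcf"), "vcf")
  }

  # --- phenotypes ----------------------------------------------------------
  st <- run_stage("phenotypes", report, {
    if (!is.null(config$phenotype_file)) {
      read_phenotypes(config$phenotype_file)
    } else {
      sim <- config$simulate
      covs <- simulate_covariates(n_individuals(gm),
                                  n_pcs = sim$n_pcs %||% 10,
                                  seed = base_seed + 1L)
      ph <- simulate_trait(gm, covs, sim$trait_spec, seed = base_seed + 2L,
                           name = config$trait)
      if (!is.null(sim$binary)) {
        ph <- simulate_binary(gm, ph, intercept = sim$binary$intercept,
                              log_or = sim$binary$log_or,
                              interaction_log_or = sim$binary$interaction_log_or,
                              seed = base_seed + 3L,
                              name = sim$binary$name %||% "status")
      }
      ph
    }
  })
  phenotypes <- st$value
  report$stages$phenotypes <- st$elapsed
  if (!config$trait %in% names(phenotypes)) {
    pipeline_stop("phenotypes",
                  simpleError(paste0("trait column '", config$trait,
                                     "' not present")))
  }
  write_phenotypes(phenotypes, file.path(config$outdir, "phenotypes.tsv"))
  trait_values <- phenotypes[[config$trait]]
  cov_mean <- phenotypes[, intersect(config$covariates_mean,
                                     names(phenotypes)), drop = FALSE]
  cov_var <- phenotypes[, intersect(config$covariates_var,
                                    names(phenotypes)), drop = FALSE]
  if (ncol(cov_mean) == 0) cov_mean <- NULL
  if (ncol(cov_var) == 0) cov_var <- NULL

  # --- scale test ----------------------------------------------------------
  st <- run_stage("scale_test", report, {
    scale_test(gm, trait_values, covariates = cov_mean,
               resid_covariates = cov_var,
               maf_min = config$maf_min,
               missing_rate_max = config$missing_rate_max)
  })
  scans <- st$value
  report$stages$scale_test <- st$elapsed
  excl <- table(scans$mean$reason, useNA = "no")
  report$counts$variants_excluded <- as.list(excl)
  report$counts$variants_tested <- sum(is.na(scans$mean$reason))
  write_stage_tsv(scans$mean, file.path(config$outdir, "scale_mean.tsv"),
                  "scale_test/mean", hash)
  write_stage_tsv(scans$variance,
                  file.path(config$outdir, "scale_variance.tsv"),
                  "scale_test/variance", hash)
  say("scale test: ", report$counts$variants_tested, " variants tested, ",
      sum(excl), " excluded")

  # --- vQTL calls ----------------------------------------------------------
  st <- run_stage("vqtl_calls", report, {
    call_vqtls(scans$mean, scans$variance,
               var_threshold = config$var_threshold,
               mean_threshold = config$mean_threshold)
  })
  vcalls <- st$value
  report$stages$vqtl_calls <- st$elapsed
  report$counts$vqtls_called <- sum(vcalls$is_vqtl)
  write_stage_tsv(vcalls, file.path(config$outdir, "vqtl_calls.tsv"),
                  "vqtl_calls", hash)
  say("vQTLs called: ", report$counts$vqtls_called)

  # --- candidate-gene dispersion scans -------------------------------------
  if (!is.null(config$candidate_regions)) {
    st <- run_stage("dispersion_scan", report, {
      cr <- config$candidate_regions
      res <- lapply(seq_len(nrow(cr)), function(i) {
        in_region <- gm$variants$chrom == cr$chrom[i] &
          gm$variants$pos >= cr$start[i] & gm$variants$pos <= cr$end[i]
        if (!any(in_region)) return(NULL)
        sub <- subset_variants(gm, gm$variants$id[in_region])
        out <- dispersion_scan(sub, trait_values, covariates = cov_var,
                               maf_min = 0.10)
        out$region <- paste0(cr$chrom[i], ":", cr$start[i], "-", cr$end[i])
        out
      })
      do.call(rbind, res)
    })
    dscan <- st$value
    report$stages$dispersion_scan <- st$elapsed
    if (!is.null(dscan)) {
      write_stage_tsv(dscan, file.path(config$outdir, "dispersion_scan.tsv"),
                      "dispersion_scan", hash)
      report$counts$dispersion_significant <-
        sum(dscan$significant, na.rm = TRUE)
      say("dispersion scan: ", sum(is.na(dscan$reason)), " variants, ",
          report$counts$dispersion_significant, " Bonferroni-significant")
    } else {
      report$counts$dispersion_significant <- 0L
      say("dispersion scan: no variants in candidate regions")
    }
  }

  # --- interaction scans ---------------------------------------------------
  focal <- config$focal_variants %||% vcalls$variant[vcalls$is_vqtl]
  y_int <- rint(trait_values)
  n_int_tested <- 0L
  n_int_sig <- 0L
  top_hit <- NULL
  for (fv in focal) {
    st <- run_stage("interaction_scan", report, {
      interaction_scan(gm, fv, y_int, covariates = cov_mean,
                       family = "linear",
                       maf_min = config$interaction_maf_min,
                       missing_rate_max = config$missing_rate_max)
    })
    iscan <- st$value
    report$stages[[paste0("interaction_scan_", fv)]] <- st$elapsed
    iscan <- iscan[order(iscan$p), ]
    write_stage_tsv(iscan,
                    file.path(config$outdir,
                              paste0("interactions_", fv, ".tsv")),
                    paste0("interaction_scan/", fv), hash)
    n_int_tested <- n_int_tested + sum(is.na(iscan$reason))
    n_int_sig <- n_int_sig + sum(iscan$p_bonferroni < 0.05, na.rm = TRUE)
    cand <- iscan[!is.na(iscan$p), ]
    if (nrow(cand) && (is.null(top_hit) || cand$p[1] < top_hit$p)) {
      top_hit <- cand[1, ]
    }
    say("interaction scan (", fv, "): best partner ",
        if (nrow(cand)) cand$partner[1] else "none")
  }
  report$counts$interactions_tested <- n_int_tested
  report$counts$interactions_significant <- n_int_sig
  if (length(focal) == 0) say("no focal variants: interaction stage empty")

  # --- stratified means and LD for the top pair ----------------------------
  if (!is.null(top_hit)) {
    st <- run_stage("stratified_means", report, {
      stratified_trait_means(trait_values,
                             dosage(gm, top_hit$focal),
                             dosage(gm, top_hit$partner),
                             labels = c(top_hit$focal, top_hit$partner))
    })
    write_stage_tsv(st$value,
                    file.path(config$outdir, "top_pair_strata.tsv"),
                    "stratified_means", hash)
    report$stages$stratified_means <- st$elapsed

    st <- run_stage("ld_top_pair", report, {
      ld <- em_haplotype_freqs(dosage(gm, top_hit$focal),
                               dosage(gm, top_hit$partner))
      data.frame(variant1 = top_hit$focal, variant2 = top_hit$partner,
                 method = ld$method, pAB = ld$pAB, D = ld$D,
                 Dprime = ld$Dprime, R2 = ld$R2, n = ld$n,
                 stringsAsFactors = FALSE)
    })
    write_stage_tsv(st$value, file.path(config$outdir, "top_pair_ld.tsv"),
                    "ld_top_pair", hash)
    report$stages$ld_top_pair <- st$elapsed
    report$top_interaction <- list(focal = top_hit$focal,
                                   partner = top_hit$partner,
                                   beta_int = top_hit$beta_int,
                                   p = top_hit$p)
  }

  # --- power report --------------------------------------------------------
  if (!is.null(config$power)) {
    pw <- config$power
    st <- run_stage("power", report, {
      power_curve(pw$mafs, pw$effects, n = pw$n, alpha = pw$alpha,
                  mode = pw$mode %||% "product")
    })
    write_stage_tsv(st$value, file.path(config$outdir, "power.tsv"),
                    "power", hash)
    report$stages$power <- st$elapsed
  }

  report$counts$consistency <- identical(
    report$counts$variants_tested + sum(unlist(report$counts$variants_excluded)),
    report$counts$variants_read
  )
  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
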