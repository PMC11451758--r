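#' Demonstration configuration: a cohort with one planted GxG pair
#'
#' Builds a [pipeline_config()] simulating a biobank-style cohort in which a
#' focal variant (`vq1`, alternate allele frequency 0.30) interacts with a
#' partner (`par1`, frequency 0.25) at an interaction effect of 0.5 trait-SD
#' per allele product, among unlinked background variants. The focal main
#' effect is set to -2 * 0.25 * 0.5 = -0.25, exactly cancelling the marginal
#' mean effect induced by the interaction (a suppressing-interaction pattern),
#' so the focal variant carries a variance signal without a mean signal and
#' is discoverable as a vQTL by the Scale test; the interaction scan around
#' it should then rank `par1` first. The focal variant sits inside the single
#' candidate region, so the dispersion scan exercises the candidate-gene
#' route on the same signal.
#'
#' At the default n = 20,000 the expected variance-scan Wald statistic is
#' roughly 9-10 (comfortably past the genome-wide threshold) and the
#' interaction Wald statistic roughly 28, giving the planted pair high
#' recovery probability per seed.
#'
#' @param outdir Output directory for [run_pipeline()].
#' @param seed Master seed.
#' @param n Cohort size (default 20000).
#' @param n_background Number of unlinked background variants (default 58).
#' @return A `pipeline_config`.
#' @export
demo_config <- function(outdir, seed, n = 20000, n_background = 58) {
  bg_mafs <- withr::with_seed(seed %% (2^28) + 17L,
                              stats::runif(n_background, 0.05, 0.5))
  mafs <- c(vq1 = 0.30, par1 = 0.25,
            stats::setNames(bg_mafs, paste0("bg", seq_len(n_background))))
  # focal + background variants bg1..bg8 share chrom "6" inside the candidate
  # region; the rest sit on chrom "1"
  chrom <- c("6", "1", rep(c("6", "1"),
                           c(8, max(0, n_background - 8))))[seq_along(mafs)]
  spec <- trait_spec(
    beta_mean = c(vq1 = -0.25),
    beta_int = data.frame(v1 = "vq1", v2 = "par1", beta = 0.5,
                          stringsAsFactors = FALSE),
    covariate_effects = c(age = 0.01, sex = 0.2, PC1 = 0.1),
    base_sd = 1, intercept = 10
  )
  pipeline_config(
    seed = seed, outdir = outdir,
    simulate = list(n = n, mafs = mafs, chrom = chrom, n_pcs = 10,
                    trait_spec = spec),
    candidate_regions = data.frame(chrom = "6", start = 1L, end = 10^7L,
                                   stringsAsFactors = FALSE),
    power = list(mafs = c(0.01, 0.05, 0.1), effects = c(0.05, 0.25, 0.5),
                 n = 400000, alpha = 5e-8, mode = "product")
  )
}
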