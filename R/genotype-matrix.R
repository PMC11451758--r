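#' Genotype matrix container
#'
#' Holds hard-call additive dosages (counts of the alternate allele, 0/1/2,
#' `NA` for missing) for a set of individuals at a set of variants, together
#' with variant metadata. This is the central genotype object consumed by all
#' scans and interaction models.
#'
#' @param dosages Numeric matrix, individuals in rows and variants in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per column of `dosages`. Variant ids must be unique.
#' @param individual_ids Character vector, one id per row of `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` and `individual_ids`.
#' @export
genotype_matrix <- function(dosages, variants, individual_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!is.data.frame(variants) ||
      !all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants))) {
    stop("`variants` must be a data frame with columns id, chrom, pos, ref, alt")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants) != ncol(dosages)) {
    stop("number of variant records (", nrow(variants),
         ") does not match number of dosage columns (", ncol(dosages), ")")
  }
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (length(individual_ids) != nrow(dosages)) {
    stop("length of `individual_ids` does not match number of dosage rows")
  }
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(individual_ids, variants$id)
  structure(
    list(dosages = dosages, variants = variants,
         individual_ids = as.character(individual_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_individuals(x), "individuals x",
      n_variants(x), "variants\n")
  invisible(x)
}

#' Number of individuals / variants in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(gm) nrow(gm$dosages)

#' @rdname n_individuals
#' @export
n_variants <- function(gm) ncol(gm$dosages)

#' Alternate-allele frequency and minor allele frequency
#'
#' Empirical frequencies computed from non-missing dosages.
#'
#' @param gm A `genotype_matrix`.
#' @return Named numeric vector, one entry per variant.
#' @export
allele_freq <- function(gm) colMeans(gm$dosages, na.rm = TRUE) / 2

#' @rdname allele_freq
#' @export
minor_allele_freq <- function(gm) {
  af <- allele_freq(gm)
  pmin(af, 1 - af)
}

#' Extract one variant's dosage vector
#' @param gm A `genotype_matrix`.
#' @param id Variant id.
#' @return Numeric dosage vector named by individual id.
#' @export
dosage <- function(gm, id) {
  if (!id %in% gm$variants$id) stop("unknown variant id: ", id)
  gm$dosages[, id]
}

#' Subset a genotype matrix by variant id
#' @param gm A `genotype_matrix`.
#' @param ids Variant ids to keep, in order.
#' @return A `genotype_matrix` restricted to `ids`.
#' @export
subset_variants <- function(gm, ids) {
  missing_ids <- setdiff(ids, gm$variants$id)
  if (length(missing_ids)) stop("unknown variant ids: ",
                                paste(missing_ids, collapse = ", "))
  keep <- match(ids, gm$variants$id)
  genotype_matrix(gm$dosages[, keep, drop = FALSE],
                  gm$variants[keep, , drop = FALSE],
                  gm$individual_ids)
}
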