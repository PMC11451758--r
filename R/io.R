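#' Write a genotype matrix to disk
#'
#' Two plain-text dialects are supported: a minimal VCF 4.2 with a GT-only
#' FORMAT field and 1-based positions, and a tab-separated dosage matrix
#' (rows = individuals, columns = variants, first column `individual_id`).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    df <- data.frame(individual_id = gm$individual_ids,
                     gm$dosages, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=vqtlgxg",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individual_ids), collapse = "\t")
  )
  body <- vapply(seq_len(n_variants(gm)), function(j) {
    v <- gm$variants[j, ]
    g <- gm$dosages[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix from disk
#'
#' VCF input is parsed through vcfR; only the GT field is used, `./.` is
#' recorded as missing, and multiallelic records (comma in ALT) are skipped
#' with their count reported in the `n_multiallelic_skipped` attribute.
#' Dosage-TSV input must have an `individual_id` first column and 0/1/2/NA
#' entries.
#'
#' @param path Input file path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()] (for dosage TSV, variant metadata carries
#'   placeholder chrom/pos/ref/alt since the dialect does not record them).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dosage_tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "individual_id") {
      stop("dosage TSV must have `individual_id` as its first column")
    }
    dos <- as.matrix(df[, -1, drop = FALSE])
    ids <- colnames(dos)
    variants <- data.frame(id = ids, chrom = NA_character_,
                           pos = seq_along(ids), ref = NA_character_,
                           alt = NA_character_, stringsAsFactors = FALSE)
    return(genotype_matrix(dos, variants, df$individual_id))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(multi)) {
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  code <- c(`0/0` = 0, `0/1` = 1, `1/0` = 1, `1/1` = 2,
            `0|0` = 0, `0|1` = 1, `1|0` = 1, `1|1` = 2)
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c("./.", ".|.")) return(NA_real_)
    if (!x %in% names(code)) stop("unparseable GT value: ", x)
    code[[x]]
  })
  dos <- t(dos)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, variants, rownames(dos))
  attr(gm, "n_multiallelic_skipped") <- sum(multi)
  gm
}

#' Write / read a phenotype table as TSV
#'
#' @param phenotypes Data frame with an `individual_id` column.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
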