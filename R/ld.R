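#' Pairwise linkage disequilibrium from phased haplotype counts
#'
#' Plug-in D, D' and R^2 from the four haplotype counts (nAB, nAb, naB, nab),
#' where "A"/"B" denote the alternate alleles of the two loci. D = pAB - pA pB;
#' D' = D / Dmax with Dmax = min(pA(1-pB), (1-pA)pB) for D >= 0 and
#' Dmax = min(pA pB, (1-pA)(1-pB)) for D < 0; R^2 = D^2 /
#' (pA(1-pA) pB(1-pB)).
#'
#' @param counts Numeric vector of length 4: counts of haplotypes AB, Ab, aB,
#'   ab (non-negative, positive total).
#' @return Object of class `ld_result`: list with `pAB`, `pAb`, `paB`, `pab`,
#'   `pA`, `pB`, `D`, `Dprime`, `R2`, `n` (haplotype total), `method`
#'   (`"phased"`), `converged` (`TRUE`).
#' @export
ld_from_haplotypes <- function(counts) {
  if (length(counts) != 4 || any(counts < 0)) {
    stop("`counts` must be 4 non-negative haplotype counts (AB, Ab, aB, ab)")
  }
  total <- sum(counts)
  if (total <= 0) stop("total haplotype count must be positive")
  f <- counts / total
  ld_from_freqs(f[1], f[2], f[3], f[4], n = total, method = "phased",
                converged = TRUE)
}

ld_from_freqs <- function(pAB, pAb, paB, pab, n, method, converged) {
  pA <- pAB + pAb
  pB <- pAB + paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    stop("LD is undefined at a monomorphic locus")
  }
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  structure(list(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
                 pA = pA, pB = pB, D = D, Dprime = dprime, R2 = r2,
                 n = n, method = method, converged = converged),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD (%s): D = %.4f, D' = %.4f, R2 = %.4f (pA = %.3f, pB = %.3f, n = %d)\n",
              x$method, x$D, x$Dprime, x$R2, x$pA, x$pB, as.integer(x$n)))
  invisible(x)
}

#' EM haplotype-frequency estimation from unphased genotypes
#'
#' Estimates two-locus haplotype frequencies from unphased dosages by
#' expectation-maximization over the double-heterozygote phase ambiguity,
#' starting from linkage-equilibrium frequencies and iterating expected
#' haplotype counts until the largest absolute frequency change falls below
#' `tol` (or `maxit` iterations). LD statistics are then plugged in as in
#' [ld_from_haplotypes()]. The observed-data log-likelihood is non-decreasing
#' across iterations.
#'
#' @param g1,g2 Dosage vectors (0/1/2); pairs with a missing value at either
#'   locus are dropped.
#' @param tol Convergence tolerance on haplotype frequencies (default 1e-10).
#' @param maxit Maximum EM iterations (default 1000).
#' @return An `ld_result` with `method = "em"`, a `converged` flag, and the
#'   per-iteration log-likelihood in the `loglik_trace` element.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, maxit = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 1) stop("no complete genotype pairs")
  if (stats::var(g1) == 0 || stats::var(g2) == 0) {
    stop("LD is undefined at a monomorphic locus")
  }
  # 3x3 genotype table, counts n[g1, g2]
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(g1 == i & g2 == j)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  n_dh <- tab[2, 2]  # double heterozygotes: phase ambiguous
  # unambiguous haplotype counts contributed by the other 8 cells
  base <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  loglik <- function(f) {
    pcell <- matrix(0, 3, 3)
    hap_p <- function(i) f[i]
    # genotype-cell probabilities from haplotype pairs
    pcell[1, 1] <- f["ab"]^2
    pcell[1, 2] <- 2 * f["ab"] * f["aB"]
    pcell[1, 3] <- f["aB"]^2
    pcell[2, 1] <- 2 * f["ab"] * f["Ab"]
    pcell[2, 2] <- 2 * f["AB"] * f["ab"] + 2 * f["Ab"] * f["aB"]
    pcell[2, 3] <- 2 * f["AB"] * f["aB"]
    pcell[3, 1] <- f["Ab"]^2
    pcell[3, 2] <- 2 * f["AB"] * f["Ab"]
    pcell[3, 3] <- f["AB"]^2
    sum(tab[tab > 0] * log(pcell[tab > 0]))
  }
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (denom > 0) f["AB"] * f["ab"] / denom else 0.5
    counts <- base + n_dh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    f_new <- counts / (2 * n)
    trace <- c(trace, loglik(f_new))
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  out <- ld_from_freqs(f[["AB"]], f[["Ab"]], f[["aB"]], f[["ab"]],
                       n = n, method = "em", converged = converged)
  out$loglik_trace <- trace
  out
}

#' Write pairwise LD results as TSV
#'
#' @param results A list of `ld_result` objects or a single one.
#' @param pairs Data frame with columns `variant1`, `variant2` (one row per
#'   result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(results, pairs, path) {
  if (inherits(results, "ld_result")) results <- list(results)
  out <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(variant1 = pairs$variant1[i], variant2 = pairs$variant2[i],
               method = r$method, pAB = r$pAB, D = r$D, Dprime = r$Dprime,
               R2 = r$R2, n = r$n, stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
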