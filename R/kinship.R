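#' Tabulate the genotype-sharing counts for one sample pair
#'
#' Over the SNPs called in both samples, counts the quantities the
#' KING-robust kinship estimator and the zero-IBD statistic are built from:
#' both-heterozygous SNPs, opposite-homozygote SNPs (0 vs 2), and each
#' sample's heterozygous-SNP count.
#'
#' @param dosages_a,dosages_b equal-length dosage vectors.
#' @return list with `n_het_het`, `n_opp_hom`, `n_het_a`, `n_het_b`,
#'   `n_valid`.  `n_valid = 0` marks the degenerate no-overlap case.
#' @export
pair_counts <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) {
    stop("dosage vectors differ in length")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  list(n_het_het = sum(a == 1L & b == 1L),
       n_opp_hom = sum(abs(a - b) == 2L),
       n_het_a = sum(a == 1L),
       n_het_b = sum(b == 1L),
       n_valid = length(a))
}

#' KING-robust kinship coefficient
#'
#' The moment estimator
#' `k = (n_het_het - 2 * n_opp_hom) / (n_het_a + n_het_b)`:
#' the kinship coefficient, i.e. the probability that two random alleles,
#' one from each sample, are identical by descent.  It is 0.5 for a sample
#' against itself (or a clone), about 0.25 for first-degree relatives
#' (parent-offspring and full sibs), and about 0 for unrelated samples; it
#' is robust to population structure and needs no LD pruning.  The KING
#' family also contains a `2 * min(n_het_a, n_het_b)` denominator variant,
#' available via `denominator = "min"`; both recover 0.25 for first-degree
#' pairs under HWE and the sum form is the default.
#'
#' @param counts a [pair_counts()] list.
#' @param denominator `"sum"` (default) or `"min"`.
#' @return kinship estimate, or `NA` (flagged undefined) when the
#'   denominator is zero.
#' @export
king_kinship <- function(counts, denominator = c("sum", "min")) {
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                sum = counts$n_het_a + counts$n_het_b,
                min = 2 * min(counts$n_het_a, counts$n_het_b))
  if (is.na(den) || den == 0) return(NA_real_)
  (counts$n_het_het - 2 * counts$n_opp_hom) / den
}

#' Expected opposite-homozygote rate for an unrelated pair
#'
#' Under HWE with alternate-allele frequency `p`, two unrelated samples are
#' opposite homozygotes with probability `2 p^2 (1 - p)^2`.  This is the
#' normalizer that turns a raw opposite-homozygote fraction into a zero-IBD
#' estimate.
#'
#' @param p numeric vector of allele frequencies.
#' @return numeric vector of expected rates.
#' @export
expected_opp_hom_rate <- function(p) {
  2 * p^2 * (1 - p)^2
}

#' Zero-IBD statistics for a sample pair
#'
#' `ibs0` is the raw opposite-homozygote fraction `n_opp_hom / n_valid`.
#' `ibd0_norm` divides it by the mean expected unrelated rate over the same
#' SNPs, giving an estimate of the probability that the pair shares zero
#' alleles identical by descent: about 0 for parent-offspring (who always
#' share one allele), about 0.25 for full sibs, and about 1 for unrelated
#' pairs.  Both are always reported side by side.
#'
#' @param counts a [pair_counts()] list with `n_valid > 0`.
#' @param freqs alternate-allele frequencies of the jointly called SNPs
#'   (or, equivalently, a precomputed mean expected rate via
#'   `expected_rate`).
#' @param expected_rate optional scalar overriding `mean(expected_opp_hom_rate(freqs))`.
#' @return list with `ibs0` and `ibd0_norm` (`NA` when every SNP is
#'   monomorphic, so the expected rate is zero).
#' @export
ibd0 <- function(counts, freqs = NULL, expected_rate = NULL) {
  if (counts$n_valid == 0) stop("no jointly called SNPs; pair is undefined")
  if (is.null(expected_rate)) {
    if (is.null(freqs)) stop("supply freqs or expected_rate")
    expected_rate <- mean(expected_opp_hom_rate(freqs), na.rm = TRUE)
  }
  ibs0 <- counts$n_opp_hom / counts$n_valid
  list(ibs0 = ibs0,
       ibd0_norm = if (is.na(expected_rate) || expected_rate <= 0) NA_real_
                   else ibs0 / expected_rate)
}

#' Relatedness estimates for every unordered sample pair
#'
#' Computes, for all pairs at once (via dense indicator cross-products),
#' the jointly-called SNP count, the KING-robust kinship, and the raw and
#' normalized zero-IBD statistics.  Allele frequencies for the
#' normalization are taken from the analyzed sample set itself unless
#' supplied.  Pairs with fewer than `min_valid` jointly called SNPs are
#' reported but flagged undefined (`NA` estimates), as are pairs with a
#' zero kinship denominator.
#'
#' @param gm genotype matrix with at least 2 samples.
#' @param min_valid minimum jointly-called SNP count for a defined
#'   estimate (default 100).
#' @param denominator kinship denominator variant, `"sum"` or `"min"`.
#' @param freqs optional per-SNP alternate-allele frequencies.
#' @return data frame over unordered pairs: `sample_a`, `sample_b`,
#'   `n_valid`, `n_het_het`, `n_opp_hom`, `k`, `ibs0`, `ibd0_norm`,
#'   `defined`.
#' @export
relatedness_table <- function(gm, min_valid = 100L,
                              denominator = c("sum", "min"), freqs = NULL) {
  denominator <- match.arg(denominator)
  m <- unclass(gm)
  if (nrow(m) < 2L) stop("relatedness needs at least 2 samples")
  freqs <- freqs %||% allele_frequencies(gm)
  C <- (!is.na(m)) * 1
  H <- (!is.na(m) & m == 1L) * 1
  A <- (!is.na(m) & m == 0L) * 1
  B <- (!is.na(m) & m == 2L) * 1
  NHH <- tcrossprod(H)
  NOPP <- tcrossprod(A, B)
  NOPP <- NOPP + t(NOPP)
  NV <- tcrossprod(C)
  HC <- tcrossprod(H, C)        # [a, b] = het SNPs of a among those called in b
  DEN <- switch(denominator, sum = HC + t(HC), min = 2 * pmin(HC, t(HC)))
  e <- expected_opp_hom_rate(freqs)
  e[is.na(e)] <- 0
  ESUM <- tcrossprod(sweep(C, 2L, e, `*`), C)
  ids <- rownames(m)
  ut <- which(upper.tri(NV), arr.ind = TRUE)
  n_valid <- NV[ut]
  k <- (NHH[ut] - 2 * NOPP[ut]) / DEN[ut]
  ibs0 <- NOPP[ut] / n_valid
  mean_e <- ESUM[ut] / n_valid
  ibd0_norm <- ifelse(mean_e > 0, ibs0 / mean_e, NA_real_)
  defined <- n_valid >= min_valid & is.finite(k)
  out <- data.frame(sample_a = ids[ut[, 1L]], sample_b = ids[ut[, 2L]],
                    n_valid = as.integer(n_valid),
                    n_het_het = as.integer(NHH[ut]),
                    n_opp_hom = as.integer(NOPP[ut]),
                    k = k, ibs0 = ibs0, ibd0_norm = ibd0_norm,
                    defined = defined, stringsAsFactors = FALSE)
  out$k[!defined] <- NA_real_
  out$ibs0[!is.finite(out$ibs0) | !defined] <- NA_real_
  out$ibd0_norm[!defined] <- NA_real_
  out
}
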