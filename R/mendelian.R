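#' Per-SNP Mendelian consistency of a trio
#'
#' A fully called (parent1, parent2, child) dosage triple is consistent
#' when one allele can be drawn from each parent so that the two sum to the
#' child dosage.  Because the transmissible allele set of a dosage is an
#' interval ({ref} for 0, {ref, alt} for 1, {alt} for 2), consistency
#' reduces to an interval test: the child dosage must lie between the
#' minimum and maximum achievable allele sums.  Of the 27 fully called
#' combinations, 12 are inconsistent.  A SNP with any missing member is
#' untestable.
#'
#' @param g_parent1,g_parent2,g_child equal-length dosage vectors.
#' @return character vector over SNPs: `"consistent"`, `"inconsistent"` or
#'   `"untestable"`.
#' @export
trio_consistent <- function(g_parent1, g_parent2, g_child) {
  n <- length(g_child)
  if (length(g_parent1) != n || length(g_parent2) != n) {
    stop("genotype vectors differ in length")
  }
  lo <- (g_parent1 == 2L) + (g_parent2 == 2L)
  hi <- (g_parent1 >= 1L) + (g_parent2 >= 1L)
  status <- rep("untestable", n)
  ok <- !is.na(g_parent1) & !is.na(g_parent2) & !is.na(g_child)
  status[ok] <- ifelse(g_child[ok] >= lo[ok] & g_child[ok] <= hi[ok],
                       "consistent", "inconsistent")
  status
}

#' Mendelian error rate of a trio
#'
#' Aggregates [trio_consistent()] over all SNPs of a genotype matrix.  The
#' denominator is the testable SNPs (called in all three samples), not the
#' total; a trio with no testable SNP is flagged undefined.  True trios
#' show error rates near the genotyping error rate; unrelated triples sit
#' far above the 1.5% confirmation ceiling used downstream.
#'
#' @param gm genotype matrix.
#' @param offspring,parent1,parent2 sample ids, all distinct (a trio
#'   containing two identical ids -- e.g. a sample paired with its own
#'   clone representative -- is rejected).
#' @return one-row data frame: `offspring`, `parent1`, `parent2`,
#'   `n_testable`, `n_inconsistent`, `error_rate`.
#' @export
trio_error_rate <- function(gm, offspring, parent1, parent2) {
  ids <- c(offspring, parent1, parent2)
  if (anyDuplicated(ids)) stop("trio contains a repeated sample id")
  missing_ids <- setdiff(ids, rownames(gm))
  if (length(missing_ids)) stop("samples not in matrix: ",
                                paste(missing_ids, collapse = ", "))
  m <- unclass(gm)
  st <- trio_consistent(m[parent1, ], m[parent2, ], m[offspring, ])
  n_test <- sum(st != "untestable")
  n_bad <- sum(st == "inconsistent")
  data.frame(offspring = offspring, parent1 = parent1, parent2 = parent2,
             n_testable = n_test, n_inconsistent = n_bad,
             error_rate = if (n_test > 0) n_bad / n_test else NA_real_,
             stringsAsFactors = FALSE)
}

#' Mendelian error rates for a table of trios
#'
#' @param gm genotype matrix.
#' @param trios data frame with columns `offspring`, `parent1`, `parent2`.
#' @return data frame with one [trio_error_rate()] row per trio.
#' @export
trio_error_rates <- function(gm, trios) {
  if (!nrow(trios)) {
    return(data.frame(offspring = character(), parent1 = character(),
                      parent2 = character(), n_testable = integer(),
                      n_inconsistent = integer(), error_rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(trios)), function(i) {
    trio_error_rate(gm, trios$offspring[i], trios$parent1[i], trios$parent2[i])
  }))
}

#' Duo (single-parent) error rate
#'
#' The only Mendelian impossibility visible in a parent-offspring pair is
#' an opposite-homozygote SNP, so the duo error rate is the
#' opposite-homozygote fraction over jointly called SNPs.  Error-free PO
#' duos (and clone pairs) give 0; unrelated pairs give roughly the mean
#' expected unrelated rate `2 p^2 (1-p)^2`.
#'
#' @param gm genotype matrix.
#' @param a,b distinct sample ids.
#' @return one-row data frame: `sample_a`, `sample_b`, `n_testable`,
#'   `n_opp_hom`, `error_rate`.
#' @export
duo_error_rate <- function(gm, a, b) {
  if (a == b) stop("duo requires two distinct samples")
  missing_ids <- setdiff(c(a, b), rownames(gm))
  if (length(missing_ids)) stop("samples not in matrix: ",
                                paste(missing_ids, collapse = ", "))
  m <- unclass(gm)
  cnt <- pair_counts(m[a, ], m[b, ])
  data.frame(sample_a = a, sample_b = b,
             n_testable = cnt$n_valid, n_opp_hom = cnt$n_opp_hom,
             error_rate = if (cnt$n_valid > 0) cnt$n_opp_hom / cnt$n_valid
                          else NA_real_,
             stringsAsFactors = FALSE)
}

#' Per-SNP Mendelian error rates across trios
#'
#' For each SNP, the fraction of trios that are inconsistent there among
#' the trios testable there.  This drives the per-SNP filter that removes
#' systematically faulty markers (pipeline default: remove when the rate
#' exceeds 5%).
#'
#' @param gm genotype matrix.
#' @param trios trio data frame (`offspring`, `parent1`, `parent2`).
#' @return data frame: `snp_id`, `n_testable`, `n_inconsistent`,
#'   `error_rate` (`NA` where no trio is testable).
#' @export
snp_mendelian_error_rates <- function(gm, trios) {
  m <- unclass(gm)
  n_test <- integer(ncol(m))
  n_bad <- integer(ncol(m))
  for (i in seq_len(nrow(trios))) {
    st <- trio_consistent(m[trios$parent1[i], ], m[trios$parent2[i], ],
                          m[trios$offspring[i], ])
    n_test <- n_test + (st != "untestable")
    n_bad <- n_bad + (st == "inconsistent")
  }
  data.frame(snp_id = colnames(m), n_testable = n_test,
             n_inconsistent = n_bad,
             error_rate = ifelse(n_test > 0, n_bad / n_test, NA_real_),
             stringsAsFactors = FALSE)
}

#' Remove SNPs with elevated Mendelian error
#'
#' Drops SNPs whose per-SNP Mendelian error rate across the supplied trios
#' exceeds `max_error_rate`; SNPs untestable in every trio are retained
#' (they carry no evidence either way).
#'
#' @param gm genotype matrix.
#' @param trios trio data frame.
#' @param max_error_rate maximum tolerated per-SNP rate (default 0.05).
#' @return filtered genotype matrix.
#' @export
filter_snps_by_mendelian_error <- function(gm, trios, max_error_rate = 0.05) {
  if (!nrow(trios)) return(gm)
  rates <- snp_mendelian_error_rates(gm, trios)
  keep <- is.na(rates$error_rate) | rates$error_rate <= max_error_rate
  gm[, keep, drop = FALSE]
}

#' Retain trios below an error-rate ceiling
#'
#' @param trio_results data frame from [trio_error_rates()].
#' @param max_error_rate ceiling; trios with `error_rate <= max_error_rate`
#'   are kept (known-trio screening uses 0.10, confirmation 0.015).
#'   Undefined (no-testable-SNP) trios are dropped.
#' @return filtered data frame.
#' @export
filter_trios <- function(trio_results, max_error_rate) {
  keep <- !is.na(trio_results$error_rate) &
    trio_results$error_rate <= max_error_rate
  trio_results[keep, , drop = FALSE]
}
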