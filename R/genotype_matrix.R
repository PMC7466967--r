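#' Genotype matrix container
#'
#' A `genotype_matrix` is a samples x SNPs integer matrix of alternate-allele
#' dosages: 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate), with `NA` marking a missing call.  Row names are sample ids,
#' column names are SNP ids; both must be unique.  This is the universal
#' currency of the pipeline: quality filters, identity-by-state, kinship and
#' Mendelian tests all consume it.
#'
#' @param dosages matrix (or coercible) of dosage codes in `{0, 1, 2, NA}`.
#' @param sample_ids,snp_ids optional character vectors overriding the
#'   dimnames of `dosages`.  When absent entirely, ids `S001...` / `snp00001...`
#'   are generated.
#' @return an object of class `genotype_matrix` (an integer matrix).
#' @examples
#' gm <- genotype_matrix(rbind(a = c(0, 1, 2), b = c(2, 1, NA)))
#' allele_frequencies(gm)
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!is.null(sample_ids)) rownames(dosages) <- as.character(sample_ids)
  if (!is.null(snp_ids)) colnames(dosages) <- as.character(snp_ids)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%05d", seq_len(ncol(dosages)))
  }
  gm <- structure(dosages, class = c("genotype_matrix", "matrix", "array"))
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks the container invariants: every dosage is 0, 1, 2 or `NA`; sample
#' and SNP ids are unique; dimensions match the id lists.
#'
#' @param gm object to validate.
#' @return `gm`, invisibly; errors describe the first violated invariant.
#' @export
validate_genotype_matrix <- function(gm) {
  if (!is.matrix(gm)) stop("genotype matrix must be a matrix")
  vals <- unclass(gm)
  bad <- vals[!is.na(vals)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    stop("dosages must be 0, 1, 2 or NA; found: ",
         paste(utils::head(setdiff(unique(bad), 0:2)), collapse = ", "))
  }
  if (anyDuplicated(rownames(gm))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(gm))) stop("duplicated SNP ids")
  invisible(gm)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out)) {
    class(out) <- c("genotype_matrix", "matrix", "array")
  }
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  m <- unclass(x)
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(m), ncol(m), 100 * mean(is.na(m))))
  if (nrow(m) && ncol(m)) {
    print(m[seq_len(min(5L, nrow(m))),
            seq_len(min(8L, ncol(m))), drop = FALSE])
    if (nrow(m) > 5L || ncol(m) > 8L) cat("...\n")
  }
  invisible(x)
}

#' Per-SNP missing fraction
#'
#' @param gm genotype matrix.
#' @return named numeric vector, fraction of samples with a missing call at
#'   each SNP.
#' @export
snp_missing_fraction <- function(gm) {
  colMeans(is.na(unclass(gm)))
}

#' Per-sample call rate
#'
#' @param gm genotype matrix.
#' @return named numeric vector, fraction of non-missing genotypes per sample.
#' @export
sample_call_rate <- function(gm) {
  rowMeans(!is.na(unclass(gm)))
}

#' Alternate-allele frequencies
#'
#' Frequency of the alternate allele at each SNP, computed over called
#' samples only: `sum(dosage) / (2 * n_called)`.  SNPs with zero called
#' samples yield `NaN` (the flagged, undefined case).
#'
#' @param gm genotype matrix.
#' @return named numeric vector in `[0, 1]` (or `NaN`).
#' @export
allele_frequencies <- function(gm) {
  m <- unclass(gm)
  colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
}

#' Per-SNP quality report
#'
#' @param gm genotype matrix.
#' @return list with `snp_missing` (per-SNP missing fraction), `call_rate`
#'   (per-sample), and `maf` (per-SNP minor-allele frequency, in `[0, 0.5]`).
#' @export
snp_qc_report <- function(gm) {
  p <- allele_frequencies(gm)
  list(snp_missing = snp_missing_fraction(gm),
       call_rate = sample_call_rate(gm),
       maf = pmin(p, 1 - p))
}

#' Filter SNPs by missing-data fraction
#'
#' Retains exactly the SNPs whose missing fraction is at or below the
#' threshold; the sample set is unchanged.  The repository-curation default
#' elsewhere in the pipeline removes SNPs with more than 2% missing data.
#'
#' @param gm genotype matrix.
#' @param max_missing_fraction maximum tolerated per-SNP missing fraction,
#'   in `[0, 1]`.
#' @return filtered genotype matrix.
#' @export
filter_snps_by_missingness <- function(gm, max_missing_fraction) {
  stopifnot(is.numeric(max_missing_fraction),
            length(max_missing_fraction) == 1L,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  keep <- snp_missing_fraction(gm) <= max_missing_fraction
  gm[, keep, drop = FALSE]
}

#' Filter samples by call rate
#'
#' Retains samples whose fraction of non-missing genotypes is at or above
#' the threshold.  A generic per-sample analogue of array QC call-rate
#' screening (pipeline default 0.96385).
#'
#' @param gm genotype matrix.
#' @param min_call_rate minimum call rate, in `[0, 1]`.
#' @return filtered genotype matrix; warns when every sample is removed.
#' @export
filter_samples_by_call_rate <- function(gm, min_call_rate) {
  stopifnot(is.numeric(min_call_rate), length(min_call_rate) == 1L,
            min_call_rate >= 0, min_call_rate <= 1)
  keep <- sample_call_rate(gm) >= min_call_rate
  if (!any(keep)) {
    warning("all samples fall below the call-rate threshold")
  }
  gm[keep, , drop = FALSE]
}
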