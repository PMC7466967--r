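#' Pairwise identity-by-state
#'
#' IBS between two samples is the mean, over SNPs called in both, of
#' `(2 - |dosage_a - dosage_b|) / 2`: 1 for identical genotypes, 0.5 for a
#' het/hom difference, 0 for opposite homozygotes.  Pairs with no shared
#' called SNP are undefined (`NA` IBS) and flagged by `n_shared = 0`.
#'
#' @param gm genotype matrix with at least 2 samples.
#' @return data frame over all unordered pairs: `sample_a`, `sample_b`,
#'   `ibs`, `n_shared`.
#' @seealso [ibs_matrix()] for the square symmetric form.
#' @export
pairwise_ibs <- function(gm) {
  M <- ibs_matrix(gm)
  NV <- attr(M, "n_shared")
  ids <- rownames(M)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  data.frame(sample_a = ids[ut[, 1L]], sample_b = ids[ut[, 2L]],
             ibs = M[ut], n_shared = NV[ut],
             stringsAsFactors = FALSE)
}

#' @rdname pairwise_ibs
#' @return `ibs_matrix()` returns the square symmetric IBS matrix (diagonal
#'   1) with the pairwise shared-SNP counts in attribute `n_shared`.
#' @export
ibs_matrix <- function(gm) {
  m <- unclass(gm)
  if (nrow(m) < 2L) stop("IBS needs at least 2 samples")
  C <- (!is.na(m)) * 1
  I0 <- (!is.na(m) & m == 0L) * 1
  I1 <- (!is.na(m) & m == 1L) * 1
  I2 <- (!is.na(m) & m == 2L) * 1
  N01 <- tcrossprod(I0, I1)
  N12 <- tcrossprod(I1, I2)
  N02 <- tcrossprod(I0, I2)
  # sum over shared SNPs of |dosage difference|
  absdiff <- N01 + t(N01) + N12 + t(N12) + 2 * (N02 + t(N02))
  NV <- tcrossprod(C)
  M <- 1 - absdiff / (2 * NV)     # NV = 0 -> NaN, i.e. undefined
  M[NV == 0] <- NA_real_
  diag(M) <- ifelse(diag(NV) > 0, 1, NA_real_)
  storage.mode(NV) <- "integer"
  attr(M, "n_shared") <- NV
  M
}

#' Calibrate the duplicate-detection IBS threshold from replicates
#'
#' Declared biological/technical replicate pairs bound how low IBS can go
#' for samples that are truly the same genotype; the threshold is the
#' minimum IBS observed among them, reported alongside the full
#' distribution.  Callers may override with a fixed value (0.977 is the
#' pipeline default when no replicates are available).  A replicate pair
#' with implausibly low IBS (< 0.95) still sets the threshold but triggers
#' a loud warning, since it is more likely a mislabeled pair than a real
#' replicate.
#'
#' @param replicate_ibs numeric vector of replicate-pair IBS values, or a
#'   data frame with an `ibs` column (as from [pairwise_ibs()]).
#' @return list with `threshold`, `n_pairs` and the sorted `ibs` values.
#' @export
calibrate_ibs_threshold <- function(replicate_ibs) {
  if (is.data.frame(replicate_ibs)) replicate_ibs <- replicate_ibs$ibs
  replicate_ibs <- replicate_ibs[!is.na(replicate_ibs)]
  if (!length(replicate_ibs)) stop("no replicate pairs with defined IBS")
  thr <- min(replicate_ibs)
  if (thr < 0.95) {
    warning(sprintf(paste("replicate pair with IBS %.3f is implausibly low;",
                          "check for mislabeled replicates before trusting",
                          "this threshold"), thr))
  }
  list(threshold = thr, n_pairs = length(replicate_ibs),
       ibs = sort(replicate_ibs))
}

#' Group duplicated samples by thresholded IBS
#'
#' Builds the graph whose edges are pairs with `ibs >= threshold` and takes
#' connected components (single linkage), so "identical to" is treated as
#' transitive; samples without any such edge are singleton groups.  Pairs
#' with undefined IBS contribute no edge.
#'
#' @param pairs data frame from [pairwise_ibs()].
#' @param threshold IBS threshold in `(0, 1]` (pipeline default 0.977).
#' @param samples optional character vector fixing the sample universe
#'   (defaults to all ids appearing in `pairs`).
#' @return data frame `sample_id`, `group_id`; group ids are the
#'   lexicographically smallest member of each group.
#' @export
find_duplicate_groups <- function(pairs, threshold, samples = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  samples <- samples %||% sort(unique(c(pairs$sample_a, pairs$sample_b)))
  keep <- !is.na(pairs$ibs) & pairs$ibs >= threshold
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("sample_a", "sample_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = samples))
  comp <- igraph::components(g)$membership
  grp <- vapply(split(names(comp), comp), min, character(1L))
  data.frame(sample_id = names(comp),
             group_id = unname(grp[as.character(comp)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pick one representative per duplicate group
#'
#' The representative is the group member with the fewest missing
#' genotypes (the best-genotyped copy); ties break to the
#' lexicographically smallest sample id.
#'
#' @param groups data frame from [find_duplicate_groups()].
#' @param gm genotype matrix containing all grouped samples.
#' @return `groups` with added columns `n_missing`, `is_representative`.
#' @export
select_representatives <- function(groups, gm) {
  miss <- rowSums(is.na(unclass(gm)))
  if (!all(groups$sample_id %in% names(miss))) {
    stop("groups contain samples absent from the genotype matrix")
  }
  groups$n_missing <- unname(miss[groups$sample_id])
  ord <- order(groups$group_id, groups$n_missing, groups$sample_id)
  groups <- groups[ord, , drop = FALSE]
  groups$is_representative <- !duplicated(groups$group_id)
  rownames(groups) <- NULL
  groups
}

#' Collapse duplicate groups to their representatives
#'
#' @param gm genotype matrix.
#' @param groups output of [select_representatives()].
#' @return list with `genotypes` (representatives only) and `rep_of`
#'   (named character vector mapping every sample to its representative).
#' @export
collapse_duplicates <- function(gm, groups) {
  if (!"is_representative" %in% names(groups)) {
    groups <- select_representatives(groups, gm)
  }
  reps <- groups$sample_id[groups$is_representative]
  rep_by_group <- stats::setNames(reps, groups$group_id[groups$is_representative])
  rep_of <- stats::setNames(unname(rep_by_group[groups$group_id]),
                            groups$sample_id)
  list(genotypes = gm[rownames(gm) %in% reps, , drop = FALSE],
       rep_of = rep_of)
}
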