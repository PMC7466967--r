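#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP gets an alternate-allele frequency `p` drawn uniformly from
#' `maf_range`; founder dosages are then independent draws from
#' `Binomial(2, p)` (i.e. genotype probabilities `q^2, 2pq, p^2`).  Loci are
#' unlinked: there is no LD, which is the clean regime for the KING-robust
#' estimator downstream.
#'
#' @param n number of founders (>= 1).
#' @param n_snps number of SNPs (>= 1).
#' @param maf_range length-2 numeric, low/high allele frequency in `(0, 0.5]`
#'   (low <= high; a degenerate range fixes `p`).
#' @param seed optional integer; fixes all randomness and restores the
#'   caller's RNG state afterwards.
#' @param sample_ids optional ids (default `FND001`, ...).
#' @return a [genotype_matrix()] with the per-SNP frequencies in attribute
#'   `true_freqs`.
#' @export
simulate_founders <- function(n, n_snps, maf_range = c(0.05, 0.5), seed = NULL,
                              sample_ids = NULL) {
  stopifnot(n >= 1, n_snps >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  with_seed(seed, {
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    m <- matrix(stats::rbinom(n * n_snps, 2L, rep(p, each = n)), nrow = n)
    gm <- genotype_matrix(m,
                          sample_ids = sample_ids %||% sprintf("FND%03d", seq_len(n)),
                          snp_ids = sprintf("snp%05d", seq_len(n_snps)))
    attr(gm, "true_freqs") <- p
    gm
  })
}

#' Simulate one offspring by Mendelian transmission
#'
#' At each SNP one allele is sampled uniformly from each parent's two
#' alleles, independently across SNPs.  Where either parent is missing the
#' offspring call is missing.
#'
#' @param g_parent1,g_parent2 equal-length dosage vectors in `{0, 1, 2, NA}`.
#' @param seed optional integer seed.
#' @return integer dosage vector of the same length.
#' @export
simulate_offspring <- function(g_parent1, g_parent2, seed = NULL) {
  if (length(g_parent1) != length(g_parent2)) {
    stop("parent genotype vectors differ in length")
  }
  with_seed(seed, {
    out <- rep(NA_integer_, length(g_parent1))
    ok <- !is.na(g_parent1) & !is.na(g_parent2)
    n <- sum(ok)
    if (n) {
      # P(transmit alternate) = dosage / 2 for each parent independently
      out[ok] <- stats::rbinom(n, 1L, g_parent1[ok] / 2) +
        stats::rbinom(n, 1L, g_parent2[ok] / 2)
    }
    out
  })
}

#' Corrupt a genotype matrix with missingness and genotyping error
#'
#' Independently per genotype: with probability `missing_rate` the call is
#' set missing; otherwise with probability `genotype_error_rate` the dosage
#' is replaced by one of the two other dosage values, chosen uniformly.
#' This symmetric replacement model produces opposite-homozygote artifacts
#' at a controllable rate, which is what the duplicate, kinship and
#' Mendelian error filters must absorb.
#'
#' @param gm genotype matrix.
#' @param genotype_error_rate,missing_rate per-genotype probabilities in
#'   `[0, 1]`.
#' @param seed optional integer seed.
#' @return corrupted genotype matrix.
#' @export
corrupt <- function(gm, genotype_error_rate, missing_rate, seed = NULL) {
  stopifnot(genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    m <- unclass(gm)
    n <- length(m)
    if (n == 0L) return(gm)
    drop <- stats::rbinom(n, 1L, missing_rate) == 1L
    err <- stats::rbinom(n, 1L, genotype_error_rate) == 1L & !drop & !is.na(m)
    if (any(err)) {
      # the two wrong dosages are (d+1) mod 3 and (d+2) mod 3
      shift <- 1L + stats::rbinom(sum(err), 1L, 0.5)
      m[err] <- (m[err] + shift) %% 3L
    }
    m[drop] <- NA_integer_
    out <- genotype_matrix(m)
    attr(out, "snp_info") <- attr(gm, "snp_info")
    out
  })
}

#' Simulation configuration
#'
#' Bundles everything [build_pedigree()] needs: founder cohort size, SNP
#' count, the allele-frequency range, an ordered crossing plan (rows are
#' executed in order, so later crosses may use earlier offspring --
#' multi-generation pedigrees, including inbred crosses, are expressed
#' naturally), a clone plan, and the corruption rates.
#'
#' @param n_founders number of founders.
#' @param n_snps number of SNPs.
#' @param maf_range allele-frequency range in `(0, 0.5]`.
#' @param crossing_plan data frame with columns `parent1`, `parent2`,
#'   `n_offspring`; parents must reference founders or previously created
#'   offspring (dangling or self references are rejected at build time).
#' @param clone_plan data frame with columns `source`, `n_copies`, or `NULL`.
#' @param genotype_error_rate,missing_rate per-genotype corruption rates.
#' @param seed integer; fixes all randomness of the build.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_founders, n_snps, maf_range = c(0.05, 0.5),
                       crossing_plan = NULL, clone_plan = NULL,
                       genotype_error_rate = 0, missing_rate = 0, seed = 1L) {
  stopifnot(n_founders >= 1, n_snps >= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(crossing_plan)) {
    stopifnot(all(c("parent1", "parent2", "n_offspring") %in% names(crossing_plan)))
  }
  if (!is.null(clone_plan)) {
    stopifnot(all(c("source", "n_copies") %in% names(clone_plan)))
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 crossing_plan = crossing_plan,
                 clone_plan = clone_plan,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default desk-scale simulation scenario
#'
#' A 200-sample, 10,000-SNP, three-generation pedigree: 60 founders, 40
#' founder crosses with two offspring each (80 F1), 25 second-round crosses
#' drawing parents from the F1 (and occasionally a founder, as in real
#' breeding programs) with two offspring each (50 F2), plus 10 clonal
#' copies spread over six sources (one "heritage cultivar" with three
#' copies, mimicking heavily duplicated accessions).  Genotyping error
#' 0.002 and missingness 0.01 per call.  The crossing plan itself is drawn
#' deterministically from `seed`.
#'
#' @param seed integer seed (also used by [build_pedigree()]).
#' @return a `sim_config`.
#' @export
default_sim_config <- function(seed = 42L) {
  with_seed(seed, {
    founders <- sprintf("FND%03d", 1:60)
    pick_pair <- function(pool) sample(pool, 2L)
    g1 <- t(vapply(1:40, function(i) pick_pair(founders), character(2L)))
    f1 <- sprintf("OFF%03d", 1:80)
    # second round: mostly F1 x F1, some F1 x founder
    g2 <- t(vapply(1:25, function(i) {
      a <- sample(f1, 1L)
      b <- if (stats::runif(1) < 0.5) sample(setdiff(f1, a), 1L) else sample(founders, 1L)
      c(a, b)
    }, character(2L)))
    plan <- data.frame(parent1 = c(g1[, 1], g2[, 1]),
                       parent2 = c(g1[, 2], g2[, 2]),
                       n_offspring = 2L, stringsAsFactors = FALSE)
    clone_src <- c(sample(founders, 3L), sample(f1, 3L))
    clones <- data.frame(source = clone_src,
                         n_copies = c(3L, 2L, 2L, 1L, 1L, 1L),
                         stringsAsFactors = FALSE)
    sim_config(n_founders = 60L, n_snps = 10000L, maf_range = c(0.05, 0.5),
               crossing_plan = plan, clone_plan = clones,
               genotype_error_rate = 0.002, missing_rate = 0.01, seed = seed)
  })
}

#' Build a synthetic pedigree with planted truth
#'
#' Simulates founders, executes the crossing plan generation by generation,
#' appends clonal copies, then applies corruption; the truth tables record
#' the exact plan.  Sample metadata (taxon, origin year by generation,
#' replicate group for clone sets) is generated alongside, so duo
#' orientation by origin year can be exercised.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (corrupted [genotype_matrix()]), `truth`
#'   (a `truth_tables` list: `parent_map`, `duplicate_groups`, `founders`),
#'   and `meta` (sample metadata data frame).
#' @export
build_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    founders <- simulate_founders(config$n_founders, config$n_snps,
                                  config$maf_range)
    m <- unclass(founders)
    generation <- stats::setNames(rep(0L, nrow(m)), rownames(m))
    plan <- config$crossing_plan
    parent_map <- data.frame(child = character(), parent1 = character(),
                             parent2 = character(), stringsAsFactors = FALSE)
    off_i <- 0L
    if (!is.null(plan)) {
      for (r in seq_len(nrow(plan))) {
        p1 <- plan$parent1[r]; p2 <- plan$parent2[r]
        if (!all(c(p1, p2) %in% rownames(m))) {
          stop("crossing plan references unknown parent(s): ",
               paste(setdiff(c(p1, p2), rownames(m)), collapse = ", "))
        }
        if (p1 == p2) stop("self-cross in crossing plan: ", p1)
        for (k in seq_len(plan$n_offspring[r])) {
          off_i <- off_i + 1L
          id <- sprintf("OFF%03d", off_i)
          m <- rbind(m, simulate_offspring(m[p1, ], m[p2, ]))
          rownames(m)[nrow(m)] <- id
          generation[id] <- max(generation[p1], generation[p2]) + 1L
          parent_map <- rbind(parent_map,
                              data.frame(child = id, parent1 = p1, parent2 = p2,
                                         stringsAsFactors = FALSE))
        }
      }
    }
    # clonal copies: exact genotype copies (corruption later differentiates)
    dup <- data.frame(sample_id = rownames(m), group_id = rownames(m),
                      stringsAsFactors = FALSE)
    if (!is.null(config$clone_plan)) {
      for (r in seq_len(nrow(config$clone_plan))) {
        src <- config$clone_plan$source[r]
        if (!src %in% rownames(m)) stop("clone plan references unknown source: ", src)
        for (k in seq_len(config$clone_plan$n_copies[r])) {
          id <- sprintf("%s_cl%d", src, k)
          m <- rbind(m, m[src, ])
          rownames(m)[nrow(m)] <- id
          generation[id] <- generation[src]
          dup <- rbind(dup, data.frame(sample_id = id, group_id = src,
                                       stringsAsFactors = FALSE))
        }
      }
    }
    gm <- genotype_matrix(m)
    founder_ids <- setdiff(rownames(m)[generation[rownames(m)] == 0L],
                           dup$sample_id[dup$sample_id != dup$group_id])
    truth <- structure(list(parent_map = parent_map,
                            duplicate_groups = dup,
                            founders = founder_ids),
                       class = "truth_tables")
    # metadata: origin years stratified by generation; clones inherit the
    # source's year and share its replicate group
    year_band <- list(`0` = 1750:1899, `1` = 1900:1949,
                      `2` = 1950:1989, `3` = 1990:2010)
    yrs <- vapply(rownames(m), function(id) {
      band <- year_band[[min(as.character(generation[id]), "3")]]
      sample(band, 1L)
    }, integer(1L))
    src_of <- stats::setNames(dup$group_id, dup$sample_id)
    clone_ids <- dup$sample_id[dup$sample_id != dup$group_id]
    yrs[clone_ids] <- yrs[src_of[clone_ids]]
    rep_grp <- rep(NA_character_, nrow(m))
    names(rep_grp) <- rownames(m)
    in_clone_set <- dup$group_id %in% src_of[clone_ids]
    rep_grp[dup$sample_id[in_clone_set]] <- dup$group_id[in_clone_set]
    meta <- data.frame(sample_id = rownames(m),
                       taxon = "Pyrus communis",
                       origin_year = unname(yrs),
                       replicate_group = unname(rep_grp),
                       stringsAsFactors = FALSE)
    genotypes <- corrupt(gm, config$genotype_error_rate, config$missing_rate)
    list(genotypes = genotypes, truth = truth, meta = meta)
  })
}

# -- benchmark cohort generators ---------------------------------------------
# Small wrappers that compose the primitives above into the standard
# validation cohorts: independent nuclear families sharing one set of SNP
# frequencies, with a named relationship pair (or trio) per family.

simulate_family_cohort <- function(n_families, n_offspring_each, n_snps,
                                   maf_range, error_rate, missing_rate, seed) {
  with_seed(seed, {
    fnd <- simulate_founders(2L * n_families, n_snps, maf_range)
    m <- unclass(fnd)
    ids_p1 <- rownames(m)[seq(1L, 2L * n_families, by = 2L)]
    ids_p2 <- rownames(m)[seq(2L, 2L * n_families, by = 2L)]
    kids <- list()
    for (i in seq_len(n_families)) {
      for (k in seq_len(n_offspring_each)) {
        kids[[sprintf("OFF%03d_%d", i, k)]] <-
          simulate_offspring(m[ids_p1[i], ], m[ids_p2[i], ])
      }
    }
    all_m <- rbind(m, do.call(rbind, kids))
    rownames(all_m) <- c(rownames(m), names(kids))
    gm <- corrupt(genotype_matrix(all_m), error_rate, missing_rate)
    list(genotypes = gm, parent1 = ids_p1, parent2 = ids_p2,
         offspring = matrix(names(kids), nrow = n_families, byrow = TRUE))
  })
}

#' Benchmark cohorts: parent-offspring pairs, full-sib pairs, clones, trios
#'
#' Convenience generators for the estimator-validation scenarios used
#' throughout the test-suite and the acceptance script: `n` independent
#' two-founder families under HWE with MAF uniform on `maf_range`, returning
#' the genotype matrix together with the relationship pairs (or trios) of
#' interest.  `simulate_clone_pairs()` instead creates one founder genotype
#' and `n` clonal copies, corrupting only the copies, so clone-source IBS
#' reflects the copy error alone.
#'
#' @param n number of pairs / trios / clones.
#' @param n_snps SNP count.
#' @param maf_range allele-frequency range.
#' @param error_rate,missing_rate per-genotype corruption rates.
#' @param seed integer seed.
#' @return list with `genotypes` and a `pairs` data frame (`sample_a`,
#'   `sample_b`) or `trios` data frame (`offspring`, `parent1`, `parent2`).
#' @export
simulate_po_pairs <- function(n = 50L, n_snps = 10000L, maf_range = c(0.05, 0.5),
                              error_rate = 0, missing_rate = 0, seed = 1L) {
  fam <- simulate_family_cohort(n, 1L, n_snps, maf_range, error_rate,
                                missing_rate, seed)
  list(genotypes = fam$genotypes,
       pairs = data.frame(sample_a = fam$parent1,
                          sample_b = fam$offspring[, 1L],
                          stringsAsFactors = FALSE))
}

#' @rdname simulate_po_pairs
#' @export
simulate_fs_pairs <- function(n = 50L, n_snps = 10000L, maf_range = c(0.05, 0.5),
                              error_rate = 0, missing_rate = 0, seed = 1L) {
  fam <- simulate_family_cohort(n, 2L, n_snps, maf_range, error_rate,
                                missing_rate, seed)
  list(genotypes = fam$genotypes,
       pairs = data.frame(sample_a = fam$offspring[, 1L],
                          sample_b = fam$offspring[, 2L],
                          stringsAsFactors = FALSE))
}

#' @rdname simulate_po_pairs
#' @export
simulate_trios <- function(n = 30L, n_snps = 10000L, maf_range = c(0.05, 0.5),
                           error_rate = 0, missing_rate = 0, seed = 1L) {
  fam <- simulate_family_cohort(n, 1L, n_snps, maf_range, error_rate,
                                missing_rate, seed)
  list(genotypes = fam$genotypes,
       trios = data.frame(offspring = fam$offspring[, 1L],
                          parent1 = fam$parent1, parent2 = fam$parent2,
                          stringsAsFactors = FALSE))
}

#' @rdname simulate_po_pairs
#' @export
simulate_clone_pairs <- function(n = 20L, n_snps = 10000L,
                                 maf_range = c(0.05, 0.5),
                                 error_rate = 0.005, seed = 1L) {
  with_seed(seed, {
    src <- simulate_founders(1L, n_snps, maf_range, sample_ids = "SRC")
    m <- unclass(src)[rep(1L, n + 1L), , drop = FALSE]
    rownames(m) <- c("SRC", sprintf("SRC_cl%d", seq_len(n)))
    clones <- corrupt(genotype_matrix(m[-1L, , drop = FALSE]), error_rate, 0)
    gm <- genotype_matrix(rbind(m[1L, , drop = FALSE], unclass(clones)))
    list(genotypes = gm,
         pairs = data.frame(sample_a = "SRC", sample_b = rownames(m)[-1L],
                            stringsAsFactors = FALSE))
  })
}
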