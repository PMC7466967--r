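#' Pipeline configuration
#'
#' Bundles every stage threshold with its curation default: SNPs with more
#' than 2% missing data are removed, samples need a call rate of at least
#' 0.96385, SNPs with a Mendelian error rate above 5% across known trios
#' are removed, known trios above 10% error are excluded from calibration,
#' the duplicate IBS threshold is 0.977, calibration coverage quantiles are
#' 0.90 then 0.95, and new relationships are confirmed below 1.5% Mendelian
#' error.
#'
#' @param sim a [sim_config()] describing a synthetic run, or `NULL` when
#'   reading real inputs.
#' @param input_genotypes,input_metadata,input_known_trios file paths used
#'   when `sim` is `NULL`.
#' @param known_trio_fraction for synthetic runs: the fraction of planted
#'   trios supplied to the reconstruction as "known" (default 0.2), drawn
#'   deterministically under `seed`.
#' @param max_snp_missing,min_sample_call_rate,max_snp_mendel_error,max_known_trio_error,ibs_threshold,q1,q2,max_trio_error,min_valid stage
#'   thresholds (see description for defaults).
#' @param k_min,ibd0_max optional fixed classification thresholds, used by
#'   the reconstruction when no known trios are available (values in the
#'   region of 0.133 and 0.005 suit well-QCed array data).
#' @param seed integer seed controlling every random choice of the run.
#' @param out_dir output directory for the stage files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL,
                            input_genotypes = NULL,
                            input_metadata = NULL,
                            input_known_trios = NULL,
                            known_trio_fraction = 0.2,
                            max_snp_missing = 0.02,
                            min_sample_call_rate = 0.96385,
                            max_snp_mendel_error = 0.05,
                            max_known_trio_error = 0.10,
                            ibs_threshold = 0.977,
                            q1 = 0.90, q2 = 0.95,
                            max_trio_error = 0.015,
                            min_valid = 100L,
                            k_min = NULL, ibd0_max = NULL,
                            seed = 42L,
                            out_dir = tempfile("kinped_run_")) {
  thresholds <- c(max_snp_missing, min_sample_call_rate, max_snp_mendel_error,
                  max_known_trio_error, ibs_threshold, q1, q2, max_trio_error,
                  known_trio_fraction)
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("all thresholds and fractions must lie in [0, 1]")
  }
  if (is.null(sim) && is.null(input_genotypes)) {
    stop("supply either a sim config or an input genotype file")
  }
  if (!is.null(input_genotypes) && !file.exists(input_genotypes)) {
    stop("input genotype file does not exist: ", input_genotypes)
  }
  structure(list(sim = sim, input_genotypes = input_genotypes,
                 input_metadata = input_metadata,
                 input_known_trios = input_known_trios,
                 known_trio_fraction = known_trio_fraction,
                 max_snp_missing = max_snp_missing,
                 min_sample_call_rate = min_sample_call_rate,
                 max_snp_mendel_error = max_snp_mendel_error,
                 max_known_trio_error = max_known_trio_error,
                 ibs_threshold = ibs_threshold,
                 q1 = q1, q2 = q2, max_trio_error = max_trio_error,
                 min_valid = as.integer(min_valid),
                 k_min = k_min, ibd0_max = ibd0_max,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments; an optional
#' `sim:` block mirrors [sim_config()] (with `default: true` requesting the
#' standard desk-scale scenario).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    if (isTRUE(y$sim$default)) {
      sim <- default_sim_config(seed = y$seed %||% 42L)
    } else {
      sim <- sim_config(
        n_founders = y$sim$n_founders, n_snps = y$sim$n_snps,
        maf_range = unlist(y$sim$maf_range) %||% c(0.05, 0.5),
        genotype_error_rate = y$sim$genotype_error_rate %||% 0,
        missing_rate = y$sim$missing_rate %||% 0,
        seed = y$sim$seed %||% (y$seed %||% 1L))
    }
  }
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

write_tsv_file <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  path
}

#' Run the full curation pipeline
#'
#' Executes simulate (or load) -> sample QC -> duplicate detection and
#' collapse -> SNP filters -> kinship -> two-round pedigree reconstruction
#' -> orientation -> evaluation (when planted truth exists), writing every
#' stage output under `config$out_dir` with fixed names and hashing each
#' file into a run manifest.  Stage outputs are pure functions of (inputs,
#' config, seed): re-running an identical config reproduces byte-identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the stage objects: `genotypes`, `truth`,
#'   `meta`, `duplicates`, `rep_of`, `genotypes_dedup`, `relatedness`,
#'   `graph`, `known_trios`, `evaluation`, `manifest`, `counts`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)
  files <- character(0)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  truth <- NULL
  meta <- NULL
  known <- NULL
  if (!is.null(config$sim)) {
    built <- build_pedigree(config$sim)
    gm <- built$genotypes
    truth <- built$truth
    meta <- built$meta
    files <- c(files, write_tsv_file(meta, out("metadata.tsv")))
    write_truth_tables(truth, out("truth"))
    files <- c(files, out(file.path("truth", "parent_map.tsv")),
               out(file.path("truth", "duplicates.tsv")))
    # a deterministic subset of planted trios plays the role of the
    # historically documented parentages
    n_known <- ceiling(config$known_trio_fraction * nrow(truth$parent_map))
    if (n_known > 0) {
      known <- with_seed(config$seed + 1L, {
        truth$parent_map[sort(sample.int(nrow(truth$parent_map), n_known)), ]
      })
      names(known) <- c("offspring", "parent1", "parent2")
    }
  } else {
    gm <- read_genotypes(config$input_genotypes)
    if (!is.null(config$input_metadata)) {
      meta <- read_sample_metadata(config$input_metadata)
    }
    if (!is.null(config$input_known_trios)) {
      known <- read_trio_list(config$input_known_trios)
    }
  }
  write_genotypes(gm, out("genotypes.vcf"), format = "vcf")
  files <- c(files, out("genotypes.vcf"))
  log_stage("input", "%d samples x %d SNPs", nrow(gm), ncol(gm))

  # sample QC
  gm_qc <- filter_samples_by_call_rate(gm, config$min_sample_call_rate)
  log_stage("sample-qc", "%d / %d samples pass call rate >= %.5f",
            nrow(gm_qc), nrow(gm), config$min_sample_call_rate)

  # duplicate detection on all QC-passed samples and SNPs
  ibs <- pairwise_ibs(gm_qc)
  M <- ibs_matrix(gm_qc)
  sq <- data.table::data.table(sample_id = rownames(M))
  sq <- cbind(sq, data.table::as.data.table(unclass(M)[, , drop = FALSE]))
  files <- c(files, write_tsv_file(sq, out("ibs.tsv")))
  groups <- find_duplicate_groups(ibs, config$ibs_threshold,
                                  samples = rownames(gm_qc))
  groups <- select_representatives(groups, gm_qc)
  files <- c(files, write_tsv_file(groups, out("duplicates.tsv")))
  collapsed <- collapse_duplicates(gm_qc, groups)
  gm_rep <- collapsed$genotypes
  rep_of <- collapsed$rep_of
  log_stage("dedupe", "%d unique genotypes in %d groups (threshold %.3f)",
            nrow(gm_rep), length(unique(groups$group_id)),
            config$ibs_threshold)

  # SNP filters: missing data, then Mendelian error over known trios
  gm_f <- filter_snps_by_missingness(gm_rep, config$max_snp_missing)
  log_stage("snp-missing", "%d / %d SNPs pass missingness <= %.2f",
            ncol(gm_f), ncol(gm_rep), config$max_snp_missing)
  known_rep <- NULL
  if (!is.null(known) && nrow(known)) {
    known_rep <- data.frame(
      offspring = unname(rep_of[known$offspring]),
      parent1 = unname(rep_of[known$parent1]),
      parent2 = unname(rep_of[known$parent2]),
      stringsAsFactors = FALSE)
    ok <- !is.na(known_rep$offspring) & !is.na(known_rep$parent1) &
      known_rep$offspring != known_rep$parent1 &
      (is.na(known_rep$parent2) |
         (known_rep$parent2 != known_rep$offspring &
            known_rep$parent2 != known_rep$parent1))
    known_rep <- known_rep[ok, , drop = FALSE]
    full_known <- known_rep[!is.na(known_rep$parent2), , drop = FALSE]
    if (nrow(full_known)) {
      gm_f <- filter_snps_by_mendelian_error(gm_f, full_known,
                                             config$max_snp_mendel_error)
    }
    log_stage("snp-mendel", "%d SNPs retained after Mendelian filter over %d known trios",
              ncol(gm_f), nrow(full_known))
  }

  # kinship + two-round reconstruction
  rel <- relatedness_table(gm_f, min_valid = config$min_valid)
  files <- c(files, write_tsv_file(rel, out("kinship.tsv")))
  rconf <- reconstruction_config(q1 = config$q1, q2 = config$q2,
                                 max_trio_error = config$max_trio_error,
                                 max_known_trio_error = config$max_known_trio_error,
                                 min_valid = config$min_valid,
                                 k_min = config$k_min,
                                 ibd0_max = config$ibd0_max)
  graph <- iterate_reconstruction(gm_f, known_trios = known_rep,
                                  config = rconf, meta = meta)
  log_stage("reconstruct", "%d trios, %d duos, %d founders",
            NROW(graph$trios), NROW(graph$duos),
            length(find_founders(graph)))
  trios_out <- graph$trios
  if (is.null(trios_out) || !nrow(trios_out)) {
    trios_out <- data.frame(offspring = character(), parent1 = character(),
                            parent2 = character(), n_testable = integer(),
                            error_rate = numeric(), n_alternates = integer(),
                            round = integer(), stringsAsFactors = FALSE)
  }
  files <- c(files, write_tsv_file(trios_out, out("trios.tsv")))
  export_pedigree(graph, out("pedigree.helium.tsv"), format = "helium")
  export_pedigree(graph, out("edges.tsv"), format = "edgelist")
  files <- c(files, out("pedigree.helium.tsv"), out("edges.tsv"))

  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate(graph, groups, truth, rep_of)
    jsonlite::write_json(evaluation, out("evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    files <- c(files, out("evaluation.json"))
  }

  counts <- list(samples_in = nrow(gm), samples_qc = nrow(gm_qc),
                 unique_genotypes = nrow(gm_rep),
                 snps_in = ncol(gm), snps_final = ncol(gm_f),
                 pairs_classified = NROW(graph$calls),
                 trios_confirmed = NROW(graph$trios),
                 duos_confirmed = NROW(graph$duos),
                 founders = length(find_founders(graph)))
  manifest <- list(
    config = config[setdiff(names(config), c("sim", "out_dir"))],
    sim_seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    counts = counts,
    hashes = as.list(tools::md5sum(sort(files))))
  names(manifest$hashes) <- substring(sort(files),
                                      nchar(config$out_dir) + 2L)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")

  invisible(list(genotypes = gm, truth = truth, meta = meta,
                 duplicates = groups, rep_of = rep_of,
                 genotypes_dedup = gm_f, relatedness = rel, graph = graph,
                 known_trios = known_rep, evaluation = evaluation,
                 manifest = manifest, counts = counts))
}

#' Score an inferred pedigree against planted truth
#'
#' Computes the acceptance surface of a synthetic run: the fraction of
#' true duplicate groups recovered exactly; precision and recall of
#' confirmed PO pairs; recall of full trios; and the Jaccard overlap of
#' the inferred founder set with the truth founders (restricted to
#' founders with at least one genotyped offspring, since childless
#' founders are invisible to the graph).  All truth relations are mapped
#' through the duplicate representatives before comparison; pairs whose
#' two members collapse to the same representative are dropped.
#'
#' @param graph inferred `pedigree_graph`.
#' @param duplicate_groups groups table from [select_representatives()].
#' @param truth planted `truth_tables`.
#' @param rep_of named vector mapping samples to representatives (from
#'   [collapse_duplicates()]); identity when omitted.
#' @return list with `duplicate_exact_match`, `po_precision`, `po_recall`,
#'   `trio_recall`, `founder_jaccard`, `founders_match` and the underlying
#'   counts.
#' @export
evaluate <- function(graph, duplicate_groups, truth, rep_of = NULL) {
  if (is.null(rep_of)) {
    ids <- unique(c(truth$duplicate_groups$sample_id, graph$nodes))
    rep_of <- stats::setNames(ids, ids)
  }
  map <- function(x) unname(rep_of[x])

  # duplicate partition agreement: fraction of truth groups whose member
  # set is exactly an inferred group
  truth_part <- split(truth$duplicate_groups$sample_id,
                      truth$duplicate_groups$group_id)
  truth_part <- truth_part[vapply(truth_part, function(g)
    all(g %in% duplicate_groups$sample_id), logical(1L))]
  inf_part <- split(duplicate_groups$sample_id, duplicate_groups$group_id)
  inf_keys <- vapply(inf_part, function(g) paste(sort(g), collapse = "|"),
                     character(1L))
  truth_keys <- vapply(truth_part, function(g) paste(sort(g), collapse = "|"),
                       character(1L))
  dup_match <- if (length(truth_keys)) mean(truth_keys %in% inf_keys) else NA_real_

  # PO pairs
  pm <- truth$parent_map
  tp <- rbind(data.frame(a = pm$child, b = pm$parent1, stringsAsFactors = FALSE),
              data.frame(a = pm$child, b = pm$parent2, stringsAsFactors = FALSE))
  tp <- tp[!is.na(tp$b), , drop = FALSE]
  tp$a <- map(tp$a); tp$b <- map(tp$b)
  tp <- tp[!is.na(tp$a) & !is.na(tp$b) & tp$a != tp$b, , drop = FALSE]
  truth_pairs <- unique(pair_key(tp$a, tp$b))
  e <- graph$edges
  inf_pairs <- unique(pair_key(e$parent, e$child))
  n_hit <- sum(inf_pairs %in% truth_pairs)
  po_precision <- if (length(inf_pairs)) n_hit / length(inf_pairs) else NA_real_
  po_recall <- if (length(truth_pairs)) n_hit / length(truth_pairs) else NA_real_

  # trios
  tt <- pm[!is.na(pm$parent2), , drop = FALSE]
  t_off <- map(tt$child); t_p1 <- map(tt$parent1); t_p2 <- map(tt$parent2)
  ok <- !is.na(t_off) & !is.na(t_p1) & !is.na(t_p2) &
    t_off != t_p1 & t_off != t_p2 & t_p1 != t_p2
  truth_trios <- unique(paste(t_off[ok], pmin(t_p1[ok], t_p2[ok]),
                              pmax(t_p1[ok], t_p2[ok])))
  g_tr <- graph$trios
  inf_trios <- if (!is.null(g_tr) && nrow(g_tr)) {
    unique(paste(g_tr$offspring, pmin(g_tr$parent1, g_tr$parent2),
                 pmax(g_tr$parent1, g_tr$parent2)))
  } else character(0)
  trio_recall <- if (length(truth_trios)) {
    mean(truth_trios %in% inf_trios)
  } else NA_real_

  # founders: truth founders restricted to those with >= 1 genotyped child
  has_child <- unique(c(pm$parent1, pm$parent2))
  tf <- map(intersect(truth$founders, has_child))
  tf <- sort(unique(tf[!is.na(tf)]))
  inf_f <- find_founders(graph)
  founder_jaccard <- if (length(union(tf, inf_f))) {
    length(intersect(tf, inf_f)) / length(union(tf, inf_f))
  } else NA_real_

  list(duplicate_exact_match = dup_match,
       po_precision = po_precision, po_recall = po_recall,
       trio_recall = trio_recall,
       founder_jaccard = founder_jaccard,
       founders_match = isTRUE(all.equal(tf, sort(inf_f))),
       n_truth_pairs = length(truth_pairs), n_inferred_pairs = length(inf_pairs),
       n_truth_trios = length(truth_trios), n_inferred_trios = length(inf_trios),
       n_truth_founders = length(tf), n_inferred_founders = length(inf_f))
}
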