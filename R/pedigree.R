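#' Parent-offspring pairs implied by a trio table
#'
#' @param trios data frame with `offspring`, `parent1`, `parent2` (rows
#'   with a missing `parent2` contribute a single pair).
#' @return data frame `sample_a`, `sample_b`, one row per PO pair.
#' @export
trio_po_pairs <- function(trios) {
  long <- rbind(
    data.frame(sample_a = trios$offspring, sample_b = trios$parent1,
               stringsAsFactors = FALSE),
    data.frame(sample_a = trios$offspring, sample_b = trios$parent2,
               stringsAsFactors = FALSE))
  long <- long[!is.na(long$sample_b), , drop = FALSE]
  long[!duplicated(pair_key(long$sample_a, long$sample_b)), , drop = FALSE]
}

# join k / ibd0 values from a relatedness table onto a pair list
lookup_pair_estimates <- function(rel, pairs, ibd0_stat = "ibd0_norm") {
  idx <- match(pair_key(pairs$sample_a, pairs$sample_b),
               pair_key(rel$sample_a, rel$sample_b))
  data.frame(sample_a = pairs$sample_a, sample_b = pairs$sample_b,
             k = rel$k[idx], ibd0 = rel[[ibd0_stat]][idx],
             stringsAsFactors = FALSE)
}

#' Calibrate first-degree classification thresholds from known PO pairs
#'
#' Rather than using the theoretical values (kinship 0.25; IBD0 of 0 for
#' parent-offspring), thresholds are set so that a chosen fraction of the
#' *known* parent-offspring pairs would be recovered: `k_min` is the
#' nearest-rank `(1 - q)` quantile of their kinship values (the largest
#' bound keeping at least `q` of the known pairs at or above it), and
#' `ibd0_max` the nearest-rank `q` quantile of their zero-IBD values.
#' `q = 1` degenerates to the (min k, max ibd0) of the known pairs.
#'
#' @param known_po_pairs data frame of known PO pairs (`sample_a`,
#'   `sample_b`), e.g. from [trio_po_pairs()].
#' @param rel relatedness table from [relatedness_table()].
#' @param coverage_quantile the coverage fraction `q` (round 1 default
#'   0.90, round 2 default 0.95).
#' @param ibd0_stat which zero-IBD column to calibrate on
#'   (`"ibd0_norm"`, the default, or raw `"ibs0"`).
#' @return list with `k_min`, `ibd0_max`, `quantile`, `n_pairs`,
#'   `ibd0_stat`.
#' @export
calibrate_thresholds <- function(known_po_pairs, rel, coverage_quantile = 0.90,
                                 ibd0_stat = c("ibd0_norm", "ibs0")) {
  ibd0_stat <- match.arg(ibd0_stat)
  stopifnot(coverage_quantile > 0, coverage_quantile <= 1)
  est <- lookup_pair_estimates(rel, known_po_pairs, ibd0_stat)
  est <- est[!is.na(est$k) & !is.na(est$ibd0), , drop = FALSE]
  if (nrow(est) < 5L) {
    stop("need at least 5 known PO pairs with defined estimates (have ",
         nrow(est), ")")
  }
  list(k_min = nearest_rank(est$k, 1 - coverage_quantile),
       ibd0_max = nearest_rank(est$ibd0, coverage_quantile),
       quantile = coverage_quantile, n_pairs = nrow(est),
       ibd0_stat = ibd0_stat)
}

#' Classify first-degree pairs into parent-offspring and full sibs
#'
#' Pairs with kinship at or above `k_min` are first-degree; among those,
#' pairs with zero-IBD at or below `ibd0_max` are called PO (a parent and
#' offspring always share one allele, so their IBD0 is near 0) and the rest
#' FS (IBD0 near 0.25).  All other pairs are unclassified and omitted.
#'
#' @param rel relatedness table.
#' @param thresholds list from [calibrate_thresholds()] (or manual, with
#'   `k_min`, `ibd0_max` and optionally `ibd0_stat`).
#' @return data frame of first-degree calls: `sample_a`, `sample_b`, `k`,
#'   `ibd0`, `class` (`"PO"` or `"FS"`).
#' @export
classify_pairs <- function(rel, thresholds) {
  stat <- thresholds$ibd0_stat %||% "ibd0_norm"
  ib <- rel[[stat]]
  first <- !is.na(rel$k) & rel$k >= thresholds$k_min & !is.na(ib)
  out <- data.frame(sample_a = rel$sample_a[first],
                    sample_b = rel$sample_b[first],
                    k = rel$k[first], ibd0 = ib[first],
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$ibd0 <= thresholds$ibd0_max, "PO", "FS")
  out
}

#' Assemble Mendelian-confirmed trios and duos from PO calls
#'
#' For every sample, its candidate parents are its PO partners; each
#' unordered candidate pair is trio-tested and the trios with Mendelian
#' error rate below `max_trio_error` are confirmed, the lowest error rate
#' winning when several pass (alternates are counted, not silently
#' dropped).  PO pairs not covered by any confirmed trio are then tested as
#' duos (opposite-homozygote rate below the same ceiling).
#'
#' @param calls classification table from [classify_pairs()].
#' @param gm genotype matrix the calls were computed on.
#' @param max_trio_error confirmation ceiling (default 0.015).
#' @return list with `trios` (offspring, parent1, parent2, n_testable,
#'   error_rate, n_alternates), `duos` (sample_a, sample_b, error_rate) and
#'   `po_pairs` (every PO pair covered by a confirmed trio or duo).
#' @export
assemble_trios <- function(calls, gm, max_trio_error = 0.015) {
  po <- calls[calls$class == "PO", , drop = FALSE]
  empty <- list(
    trios = data.frame(offspring = character(), parent1 = character(),
                       parent2 = character(), n_testable = integer(),
                       error_rate = numeric(), n_alternates = integer(),
                       stringsAsFactors = FALSE),
    duos = data.frame(sample_a = character(), sample_b = character(),
                      error_rate = numeric(), stringsAsFactors = FALSE),
    po_pairs = data.frame(sample_a = character(), sample_b = character(),
                          stringsAsFactors = FALSE))
  if (!nrow(po)) return(empty)
  partners <- split(c(po$sample_b, po$sample_a), c(po$sample_a, po$sample_b))
  trio_rows <- list()
  for (x in names(partners)) {
    cand <- sort(unique(partners[[x]]))
    if (length(cand) < 2L) next
    pairs <- utils::combn(cand, 2L)
    res <- lapply(seq_len(ncol(pairs)), function(j) {
      trio_error_rate(gm, x, pairs[1L, j], pairs[2L, j])
    })
    res <- do.call(rbind, res)
    pass <- !is.na(res$error_rate) & res$error_rate < max_trio_error
    if (!any(pass)) next
    res <- res[pass, , drop = FALSE]
    best <- which.min(res$error_rate)
    trio_rows[[x]] <- data.frame(
      offspring = x, parent1 = res$parent1[best], parent2 = res$parent2[best],
      n_testable = res$n_testable[best], error_rate = res$error_rate[best],
      n_alternates = nrow(res) - 1L, stringsAsFactors = FALSE)
  }
  trios <- if (length(trio_rows)) do.call(rbind, trio_rows) else empty$trios
  rownames(trios) <- NULL
  covered <- character(0)
  if (nrow(trios)) {
    covered <- c(pair_key(trios$offspring, trios$parent1),
                 pair_key(trios$offspring, trios$parent2))
  }
  po_keys <- pair_key(po$sample_a, po$sample_b)
  open <- po[!duplicated(po_keys) & !(po_keys %in% covered), , drop = FALSE]
  duo_rows <- lapply(seq_len(nrow(open)), function(i) {
    duo_error_rate(gm, open$sample_a[i], open$sample_b[i])
  })
  duos <- if (length(duo_rows)) do.call(rbind, duo_rows) else empty$duos
  duos <- duos[!is.na(duos$error_rate) & duos$error_rate < max_trio_error,
               c("sample_a", "sample_b", "error_rate"), drop = FALSE]
  rownames(duos) <- NULL
  po_pairs <- rbind(
    if (nrow(trios)) data.frame(
      sample_a = c(trios$offspring, trios$offspring),
      sample_b = c(trios$parent1, trios$parent2), stringsAsFactors = FALSE),
    duos[, c("sample_a", "sample_b"), drop = FALSE])
  po_pairs <- po_pairs %||% empty$po_pairs
  if (is.null(po_pairs) || !nrow(po_pairs)) po_pairs <- empty$po_pairs
  po_pairs <- po_pairs[!duplicated(pair_key(po_pairs$sample_a,
                                            po_pairs$sample_b)), , drop = FALSE]
  rownames(po_pairs) <- NULL
  list(trios = trios, duos = duos, po_pairs = po_pairs)
}

#' Reconstruction settings
#'
#' @param q1,q2 calibration coverage quantiles for the two search rounds
#'   (defaults 0.90 and 0.95).
#' @param max_trio_error Mendelian confirmation ceiling (default 0.015).
#' @param max_known_trio_error screening ceiling for supplied known trios
#'   (default 0.10; noisier knowns are excluded from calibration).
#' @param k_min,ibd0_max optional fixed thresholds used when no known
#'   trios are available (values in the region of 0.133 and 0.005 suit
#'   well-QCed array data).
#' @param min_valid minimum jointly-called SNPs per pair.
#' @param denominator kinship denominator variant.
#' @param ibd0_stat zero-IBD statistic used for classification.
#' @return a named list of settings for [iterate_reconstruction()].
#' @export
reconstruction_config <- function(q1 = 0.90, q2 = 0.95, max_trio_error = 0.015,
                                  max_known_trio_error = 0.10,
                                  k_min = NULL, ibd0_max = NULL,
                                  min_valid = 100L,
                                  denominator = "sum",
                                  ibd0_stat = "ibd0_norm") {
  list(q1 = q1, q2 = q2, max_trio_error = max_trio_error,
       max_known_trio_error = max_known_trio_error,
       k_min = k_min, ibd0_max = ibd0_max, min_valid = min_valid,
       denominator = denominator, ibd0_stat = ibd0_stat)
}

#' Two-round pedigree reconstruction
#'
#' The full inference procedure on a deduplicated genotype matrix:
#'
#' 1. Known trios/duos (if any) are Mendelian-screened (error rate at most
#'    `max_known_trio_error`); their PO pairs calibrate round-1 thresholds
#'    at coverage `q1`.  Without known trios, fixed `k_min` / `ibd0_max`
#'    must be supplied.
#' 2. All pairs are classified, candidate trios and duos are assembled and
#'    Mendelian-confirmed at `max_trio_error`.
#' 3. Round 2 recalibrates at coverage `q2` from the newly confirmed PO
#'    pairs, then re-classifies all pairs and confirms again.  Exactly two
#'    rounds are run; the union of confirmed relationships (plus known
#'    trios/duos that pass the confirmation ceiling themselves) forms the
#'    pedigree.
#'
#' Trio offspring edges are directed by construction; duo edges stay
#' undirected until [orient_edges()] applies origin-year metadata.  The
#' directed part of the result must be acyclic -- a cycle is a hard error,
#' not a warning.
#'
#' @param gm deduplicated genotype matrix.
#' @param known_trios optional data frame (`offspring`, `parent1`,
#'   `parent2`; `parent2` may be `NA` for duos).
#' @param config settings list from [reconstruction_config()].
#' @param meta optional sample metadata for duo orientation.
#' @return a `pedigree_graph` object.
#' @export
iterate_reconstruction <- function(gm, known_trios = NULL,
                                   config = reconstruction_config(),
                                   meta = NULL) {
  rel <- relatedness_table(gm, min_valid = config$min_valid,
                           denominator = config$denominator)
  known_pairs <- NULL
  known_conf_trios <- NULL
  known_conf_duos <- NULL
  if (!is.null(known_trios) && nrow(known_trios)) {
    full <- known_trios[!is.na(known_trios$parent2), , drop = FALSE]
    duo_in <- known_trios[is.na(known_trios$parent2), , drop = FALSE]
    tr <- trio_error_rates(gm, full)
    tr_ok <- filter_trios(tr, config$max_known_trio_error)
    du <- if (nrow(duo_in)) do.call(rbind, lapply(seq_len(nrow(duo_in)),
      function(i) duo_error_rate(gm, duo_in$offspring[i], duo_in$parent1[i])))
      else NULL
    du_ok <- if (!is.null(du)) {
      du[!is.na(du$error_rate) & du$error_rate <= config$max_known_trio_error,
         , drop = FALSE]
    } else NULL
    kp <- trio_po_pairs(data.frame(
      offspring = c(tr_ok$offspring, du_ok$sample_a),
      parent1 = c(tr_ok$parent1, du_ok$sample_b),
      parent2 = c(tr_ok$parent2, rep(NA_character_, NROW(du_ok))),
      stringsAsFactors = FALSE))
    if (nrow(kp)) known_pairs <- kp
    # knowns enter the pedigree only if they pass the stricter
    # confirmation ceiling themselves
    kc <- filter_trios(tr_ok, Inf)
    kc <- kc[kc$error_rate < config$max_trio_error, , drop = FALSE]
    if (nrow(kc)) {
      known_conf_trios <- data.frame(kc[, c("offspring", "parent1", "parent2",
                                            "n_testable", "error_rate")],
                                     n_alternates = 0L, stringsAsFactors = FALSE)
    }
    if (!is.null(du_ok)) {
      dk <- du_ok[du_ok$error_rate < config$max_trio_error, , drop = FALSE]
      if (nrow(dk)) {
        known_conf_duos <- dk[, c("sample_a", "sample_b", "error_rate")]
      }
    }
  }
  if (!is.null(known_pairs)) {
    th1 <- calibrate_thresholds(known_pairs, rel, config$q1, config$ibd0_stat)
  } else if (!is.null(config$k_min) && !is.null(config$ibd0_max)) {
    th1 <- list(k_min = config$k_min, ibd0_max = config$ibd0_max,
                quantile = NA_real_, n_pairs = 0L,
                ibd0_stat = config$ibd0_stat)
  } else {
    stop("no known trios and no fixed k_min/ibd0_max thresholds supplied")
  }
  calls1 <- classify_pairs(rel, th1)
  asm1 <- assemble_trios(calls1, gm, config$max_trio_error)
  new_pairs <- asm1$po_pairs
  if (!is.null(known_pairs) && nrow(new_pairs)) {
    new_pairs <- new_pairs[!(pair_key(new_pairs$sample_a, new_pairs$sample_b)
                             %in% pair_key(known_pairs$sample_a,
                                           known_pairs$sample_b)), ,
                           drop = FALSE]
  }
  th2 <- NULL
  asm2 <- NULL
  calls2 <- NULL
  if (!nrow(asm1$trios) && !nrow(asm1$duos)) {
    warning("no relationships confirmed in round 1; round 2 skipped")
  } else if (nrow(new_pairs) < 5L) {
    warning("fewer than 5 newly confirmed PO pairs; round 2 skipped")
  } else {
    th2 <- calibrate_thresholds(new_pairs, rel, config$q2, config$ibd0_stat)
    calls2 <- classify_pairs(rel, th2)
    asm2 <- assemble_trios(calls2, gm, config$max_trio_error)
  }
  # union of confirmed relationships across rounds (earliest round wins)
  trio_union <- rbind(
    if (!is.null(known_conf_trios)) cbind(known_conf_trios, round = 0L),
    if (nrow(asm1$trios)) cbind(asm1$trios, round = 1L),
    if (!is.null(asm2) && nrow(asm2$trios)) cbind(asm2$trios, round = 2L))
  if (!is.null(trio_union) && nrow(trio_union)) {
    # one confirmed parent pair per offspring: earliest round, then the
    # lowest Mendelian error, wins (alternates were already counted)
    ord <- order(trio_union$offspring, trio_union$round,
                 trio_union$error_rate)
    trio_union <- trio_union[ord, , drop = FALSE]
    trio_union <- trio_union[!duplicated(trio_union$offspring), , drop = FALSE]
    rownames(trio_union) <- NULL
  }
  duo_union <- rbind(
    if (!is.null(known_conf_duos)) cbind(known_conf_duos, round = 0L),
    if (nrow(asm1$duos)) cbind(asm1$duos, round = 1L),
    if (!is.null(asm2) && nrow(asm2$duos)) cbind(asm2$duos, round = 2L))
  if (!is.null(duo_union) && nrow(duo_union)) {
    duo_union <- duo_union[!duplicated(pair_key(duo_union$sample_a,
                                                duo_union$sample_b)), ,
                           drop = FALSE]
    if (!is.null(trio_union) && nrow(trio_union)) {
      tkeys <- c(pair_key(trio_union$offspring, trio_union$parent1),
                 pair_key(trio_union$offspring, trio_union$parent2))
      duo_union <- duo_union[!(pair_key(duo_union$sample_a,
                                        duo_union$sample_b) %in% tkeys), ,
                             drop = FALSE]
    }
    rownames(duo_union) <- NULL
  }
  calls_all <- rbind(
    if (nrow(calls1)) cbind(calls1, round = 1L),
    if (!is.null(calls2) && nrow(calls2)) cbind(calls2, round = 2L))
  graph <- pedigree_graph(nodes = rownames(gm), trios = trio_union,
                          duos = duo_union, rel = rel, calls = calls_all,
                          thresholds = list(round1 = th1, round2 = th2),
                          ibd0_stat = config$ibd0_stat)
  if (!is.null(meta)) graph <- orient_edges(graph, meta)
  graph
}

#' Pedigree graph
#'
#' Accessions as nodes; confirmed PO relationships as edges, directed
#' parent-to-offspring where orientable (trio edges are directed by
#' construction, duo edges only after year orientation).  The directed
#' subgraph must be acyclic and no offspring may carry more than two
#' confirmed parents; both are validated at construction.
#'
#' @param nodes character vector of sample ids.
#' @param trios,duos confirmed relationship tables (may be `NULL`).
#' @param rel optional relatedness table used to annotate edges.
#' @param calls optional classification table kept for reporting.
#' @param thresholds calibration thresholds per round.
#' @param ibd0_stat zero-IBD statistic name used in annotations.
#' @return a `pedigree_graph` list with elements `nodes`, `edges`,
#'   `trios`, `duos`, `calls`, `thresholds`.
#' @export
pedigree_graph <- function(nodes, trios = NULL, duos = NULL, rel = NULL,
                           calls = NULL, thresholds = NULL,
                           ibd0_stat = "ibd0_norm") {
  empty_edges <- data.frame(parent = character(), child = character(),
                            directed = logical(), type = character(),
                            round = integer(), error_rate = numeric(),
                            k = numeric(), ibd0 = numeric(),
                            note = character(), stringsAsFactors = FALSE)
  edges <- empty_edges
  if (!is.null(trios) && nrow(trios)) {
    edges <- rbind(edges, data.frame(
      parent = c(trios$parent1, trios$parent2),
      child = c(trios$offspring, trios$offspring),
      directed = TRUE, type = "trio",
      round = rep(trios$round %||% NA_integer_, 2L),
      error_rate = rep(trios$error_rate, 2L),
      k = NA_real_, ibd0 = NA_real_, note = "",
      stringsAsFactors = FALSE))
  }
  if (!is.null(duos) && nrow(duos)) {
    edges <- rbind(edges, data.frame(
      parent = duos$sample_a, child = duos$sample_b,
      directed = FALSE, type = "duo",
      round = duos$round %||% NA_integer_,
      error_rate = duos$error_rate,
      k = NA_real_, ibd0 = NA_real_, note = "unoriented",
      stringsAsFactors = FALSE))
  }
  if (!is.null(rel) && nrow(edges)) {
    idx <- match(pair_key(edges$parent, edges$child),
                 pair_key(rel$sample_a, rel$sample_b))
    edges$k <- rel$k[idx]
    edges$ibd0 <- rel[[ibd0_stat]][idx]
  }
  g <- structure(list(nodes = nodes, edges = edges,
                      trios = trios, duos = duos, calls = calls,
                      thresholds = thresholds),
                 class = "pedigree_graph")
  validate_pedigree_graph(g)
  g
}

validate_pedigree_graph <- function(g) {
  e <- g$edges
  bad <- setdiff(unique(c(e$parent, e$child)), g$nodes)
  if (length(bad)) stop("edges reference unknown nodes: ",
                        paste(bad, collapse = ", "))
  dir_e <- e[e$directed, , drop = FALSE]
  if (nrow(dir_e)) {
    n_par <- table(dir_e$child)
    if (any(n_par > 2L)) {
      stop("offspring with more than two confirmed parents: ",
           paste(names(n_par)[n_par > 2L], collapse = ", "))
    }
    ig <- igraph::graph_from_data_frame(dir_e[, c("parent", "child")],
                                        directed = TRUE,
                                        vertices = data.frame(name = g$nodes))
    if (!igraph::is_dag(ig)) stop("directed pedigree contains a cycle")
  }
  invisible(g)
}

#' @export
print.pedigree_graph <- function(x, ...) {
  e <- x$edges
  cat(sprintf(paste0("pedigree_graph: %d nodes, %d PO edges ",
                     "(%d directed), %d trios, %d duos, %d founders\n"),
              length(x$nodes), nrow(e), sum(e$directed),
              NROW(x$trios), NROW(x$duos), length(find_founders(x))))
  invisible(x)
}

#' Orient duo edges by origin year
#'
#' An undirected parent-offspring duo is directed old-to-young when both
#' accessions carry a documented origin year and the years differ; equal
#' years are flagged ambiguous and missing years leave the edge
#' undirected, mirroring how documented cultivar histories are actually
#' used.  An orientation that would give a child a third parent is
#' refused and flagged.
#'
#' @param graph a `pedigree_graph`.
#' @param meta sample metadata with `sample_id` and `origin_year`.
#' @return the graph with duo edges directed where the evidence allows.
#' @export
orient_edges <- function(graph, meta) {
  e <- graph$edges
  if (!nrow(e)) return(graph)
  yr <- stats::setNames(meta$origin_year, meta$sample_id)
  n_parents <- table(e$child[e$directed])
  for (i in which(!e$directed)) {
    ya <- yr[e$parent[i]]; yb <- yr[e$child[i]]
    if (is.na(ya) || is.na(yb)) { e$note[i] <- "unknown-year"; next }
    if (ya == yb) { e$note[i] <- "ambiguous-year"; next }
    parent <- if (ya < yb) e$parent[i] else e$child[i]
    child <- if (ya < yb) e$child[i] else e$parent[i]
    if (!is.na(n_parents[child]) && n_parents[child] >= 2L) {
      e$note[i] <- "would-exceed-two-parents"
      next
    }
    e$parent[i] <- parent; e$child[i] <- child
    e$directed[i] <- TRUE; e$note[i] <- "year-oriented"
    n_parents[child] <- (if (is.na(n_parents[child])) 0L else n_parents[child]) + 1L
  }
  graph$edges <- e
  validate_pedigree_graph(graph)
  graph
}

#' Founders of a pedigree graph
#'
#' Founders are accessions with no confirmed parent (no incoming directed
#' edge) and at least one confirmed offspring (an outgoing directed edge).
#'
#' @param graph a `pedigree_graph`.
#' @return character vector of founder ids (possibly empty).
#' @export
find_founders <- function(graph) {
  e <- graph$edges[graph$edges$directed, , drop = FALSE]
  if (!nrow(e)) return(character(0))
  sort(setdiff(unique(e$parent), unique(e$child)))
}

#' Export a pedigree graph
#'
#' `"helium"` writes the three-column individual/parent1/parent2 table
#' consumed by the Helium pedigree visualizer: one row per accession,
#' unknown parents blank.  (Only directed edges can fill parent slots;
#' unoriented duos are not representable in this format.)  `"edgelist"`
#' writes one row per edge with the direction flag and supporting
#' statistics.  [read_pedigree()] parses either format back to an edge
#' table, and export-then-parse preserves the edge set.
#'
#' @param graph a `pedigree_graph`.
#' @param path output file.
#' @param format `"helium"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_pedigree <- function(graph, path, format = c("helium", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    data.table::fwrite(graph$edges, path, sep = "\t", na = "", quote = FALSE)
    return(invisible(path))
  }
  e <- graph$edges[graph$edges$directed, , drop = FALSE]
  parents <- split(e$parent, e$child)
  rows <- t(vapply(graph$nodes, function(nd) {
    ps <- sort(unique(parents[[nd]] %||% character(0)))
    c(nd,
      if (length(ps) >= 1L) ps[1L] else "",
      if (length(ps) >= 2L) ps[2L] else "")
  }, character(3L)))
  lines <- c("individual\tparent1\tparent2",
             apply(rows, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_pedigree
#' @return `read_pedigree()` returns a data frame of edges (`parent`,
#'   `child`, `directed`).
#' @export
read_pedigree <- function(path, format = c("helium", "edgelist")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    e <- as.data.frame(data.table::fread(path, sep = "\t",
                                         na.strings = c("", "NA")))
    return(e[, c("parent", "child", "directed")])
  }
  tab <- as.data.frame(data.table::fread(path, sep = "\t",
                                         na.strings = c("", "NA"),
                                         colClasses = "character"))
  out <- rbind(
    data.frame(parent = tab$parent1, child = tab$individual,
               stringsAsFactors = FALSE),
    data.frame(parent = tab$parent2, child = tab$individual,
               stringsAsFactors = FALSE))
  out <- out[!is.na(out$parent), , drop = FALSE]
  out$directed <- TRUE
  rownames(out) <- NULL
  out
}
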