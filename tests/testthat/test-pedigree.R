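# helper: a relatedness table with prescribed k / ibd0 values per pair
fake_rel <- function(k, ibd0) {
  n <- length(k)
  data.frame(sample_a = sprintf("X%02d", seq_len(n)),
             sample_b = sprintf("Y%02d", seq_len(n)),
             n_valid = 1000L, n_het_het = 0L, n_opp_hom = 0L,
             k = k, ibs0 = ibd0, ibd0_norm = ibd0, defined = TRUE,
             stringsAsFactors = FALSE)
}

test_that("threshold calibration uses nearest-rank one-sided quantiles", {
  ks <- c(0.20, 0.21, 0.22, 0.23, 0.24, 0.24, 0.25, 0.25, 0.26, 0.26)
  ibs <- c(0, 0, 0, 0, 0, 0.001, 0.001, 0.001, 0.002, 0.004)
  rel <- fake_rel(ks, ibs)
  pairs <- rel[, c("sample_a", "sample_b")]
  th <- calibrate_thresholds(pairs, rel, coverage_quantile = 0.90)
  expect_equal(th$k_min, 0.20)       # 1st order statistic of 10
  expect_equal(th$ibd0_max, 0.002)   # 9th order statistic of 10
  full <- calibrate_thresholds(pairs, rel, coverage_quantile = 1.0)
  expect_equal(full$k_min, min(ks))
  expect_equal(full$ibd0_max, max(ibs))
  expect_error(calibrate_thresholds(pairs[1:4, ], rel, 0.9), "at least 5")
})

test_that("pairs classify as PO or FS against the calibrated bounds", {
  rel <- fake_rel(c(0.24, 0.24, 0.10), c(0.001, 0.20, 0))
  calls <- classify_pairs(rel, list(k_min = 0.133, ibd0_max = 0.005))
  expect_equal(nrow(calls), 2L)                       # third pair below k_min
  expect_equal(calls$class, c("PO", "FS"))
})

test_that("trio assembly confirms the best Mendelian-consistent parent pair", {
  sim <- simulate_trios(n = 3, n_snps = 3000, error_rate = 0.002, seed = 71)
  tr <- sim$trios[1, ]
  # candidate parents: the two real ones plus an unrelated founder
  distractor <- sim$trios$parent1[2]
  calls <- data.frame(sample_a = tr$offspring,
                      sample_b = c(tr$parent1, tr$parent2, distractor),
                      k = 0.25, ibd0 = 0, class = "PO",
                      stringsAsFactors = FALSE)
  asm <- assemble_trios(calls, sim$genotypes)
  expect_equal(nrow(asm$trios), 1L)
  expect_setequal(c(asm$trios$parent1, asm$trios$parent2),
                  c(tr$parent1, tr$parent2))
  expect_lt(asm$trios$error_rate, 0.015)
  expect_equal(asm$trios$n_alternates, 0L)
  # the distractor pair is not even duo-confirmable
  expect_false(distractor %in% c(asm$duos$sample_a, asm$duos$sample_b))
  # a single PO partner yields a confirmed duo instead
  solo <- data.frame(sample_a = tr$offspring, sample_b = tr$parent1,
                     k = 0.25, ibd0 = 0, class = "PO", stringsAsFactors = FALSE)
  asm2 <- assemble_trios(solo, sim$genotypes)
  expect_equal(nrow(asm2$trios), 0L)
  expect_equal(nrow(asm2$duos), 1L)
  expect_equal(asm2$duos$error_rate, duo_error_rate(
    sim$genotypes, tr$offspring, tr$parent1)$error_rate)
})

test_that("duo edges orient old-to-young only when both years are known", {
  duos <- data.frame(sample_a = c("A", "C", "E"), sample_b = c("B", "D", "F"),
                     error_rate = 0, round = 1L, stringsAsFactors = FALSE)
  g <- pedigree_graph(nodes = LETTERS[1:6], duos = duos)
  meta <- data.frame(sample_id = LETTERS[1:6],
                     origin_year = c(1770L, 1880L, 1900L, NA, 1950L, 1950L),
                     stringsAsFactors = FALSE)
  og <- orient_edges(g, meta)
  e <- og$edges
  ab <- e[pair_key(e$parent, e$child) == pair_key("A", "B"), ]
  expect_true(ab$directed)
  expect_equal(ab$parent, "A")
  cd <- e[pair_key(e$parent, e$child) == pair_key("C", "D"), ]
  expect_false(cd$directed)
  expect_equal(cd$note, "unknown-year")
  ef <- e[pair_key(e$parent, e$child) == pair_key("E", "F"), ]
  expect_false(ef$directed)
  expect_equal(ef$note, "ambiguous-year")
})

test_that("founders have confirmed offspring but no confirmed parents", {
  trios <- data.frame(offspring = "C", parent1 = "B", parent2 = "D",
                      n_testable = 100L, error_rate = 0, n_alternates = 0L,
                      round = 1L, stringsAsFactors = FALSE)
  duos <- data.frame(sample_a = "A", sample_b = "B", error_rate = 0,
                     round = 1L, stringsAsFactors = FALSE)
  g <- pedigree_graph(nodes = c("A", "B", "C", "D", "E"), trios = trios,
                      duos = duos)
  meta <- data.frame(sample_id = c("A", "B", "C", "D", "E"),
                     origin_year = c(1700L, 1800L, 1900L, 1800L, 2000L),
                     stringsAsFactors = FALSE)
  g <- orient_edges(g, meta)      # directs A -> B
  expect_setequal(find_founders(g), c("A", "D"))
  empty <- pedigree_graph(nodes = c("A", "B"))
  expect_length(find_founders(empty), 0L)
})

test_that("graph invariants are hard errors", {
  cyc <- data.frame(offspring = c("B", "A"), parent1 = c("A", "B"),
                    parent2 = c("C", "D"), n_testable = 10L, error_rate = 0,
                    n_alternates = 0L, round = 1L, stringsAsFactors = FALSE)
  expect_error(pedigree_graph(nodes = LETTERS[1:4], trios = cyc), "cycle")
  three <- data.frame(offspring = "A", parent1 = c("B", "D"),
                      parent2 = c("C", "E"), n_testable = 10L, error_rate = 0,
                      n_alternates = 0L, round = 1L, stringsAsFactors = FALSE)
  expect_error(pedigree_graph(nodes = LETTERS[1:5], trios = three),
               "more than two")
  ghost <- data.frame(sample_a = "A", sample_b = "Z", error_rate = 0,
                      round = 1L, stringsAsFactors = FALSE)
  expect_error(pedigree_graph(nodes = c("A", "B"), duos = ghost), "unknown")
})

test_that("pedigree exports round-trip in both formats", {
  trios <- data.frame(offspring = "C", parent1 = "A", parent2 = "B",
                      n_testable = 100L, error_rate = 0.001, n_alternates = 0L,
                      round = 1L, stringsAsFactors = FALSE)
  duos <- data.frame(sample_a = "C", sample_b = "D", error_rate = 0,
                     round = 2L, stringsAsFactors = FALSE)
  g <- pedigree_graph(nodes = c("A", "B", "C", "D"), trios = trios, duos = duos)
  hp <- withr::local_tempfile(fileext = ".tsv")
  export_pedigree(g, hp, "helium")
  tab <- read.delim(hp, colClasses = "character")
  expect_equal(nrow(tab), 4L)                       # every node gets a row
  expect_equal(tab$parent1[tab$individual == "C"], "A")
  expect_equal(tab$parent2[tab$individual == "C"], "B")
  expect_equal(tab$parent1[tab$individual == "A"], "")
  back <- read_pedigree(hp, "helium")
  expect_setequal(pair_key(back$parent, back$child),
                  pair_key(c("A", "B"), c("C", "C")))
  ep <- withr::local_tempfile(fileext = ".tsv")
  export_pedigree(g, ep, "edgelist")
  eback <- read_pedigree(ep, "edgelist")
  expect_setequal(pair_key(eback$parent, eback$child),
                  pair_key(g$edges$parent, g$edges$child))
  expect_equal(sum(eback$directed), 2L)
})

test_that("two-round reconstruction recovers a planted pedigree deterministically", {
  set.seed(73)
  founders <- sprintf("FND%03d", 1:30)
  g1 <- data.frame(parent1 = founders[seq(1, 29, 2)][1:12],
                   parent2 = founders[seq(2, 30, 2)][1:12], n_offspring = 3L)
  g2 <- data.frame(parent1 = sprintf("OFF%03d", 1:6),
                   parent2 = sprintf("OFF%03d", 19:24), n_offspring = 1L)
  cfg <- sim_config(30, 3000, crossing_plan = rbind(g1, g2),
                    genotype_error_rate = 0.002, missing_rate = 0.01,
                    seed = 73)
  built <- build_pedigree(cfg)
  pm <- built$truth$parent_map
  known <- pm[seq(1, nrow(pm), by = 5), ]
  names(known) <- c("offspring", "parent1", "parent2")
  graph <- iterate_reconstruction(built$genotypes, known_trios = known,
                                  meta = built$meta)
  # confirmed relationships are a subset of classified first-degree pairs
  po_calls <- unique(pair_key(graph$calls$sample_a, graph$calls$sample_b))
  new_edges <- graph$edges[!is.na(graph$edges$round) & graph$edges$round > 0, ]
  expect_true(all(pair_key(new_edges$parent, new_edges$child) %in% po_calls))
  # every inferred PO pair is a true one (precision) and most are found
  truth_keys <- unique(c(pair_key(pm$child, pm$parent1),
                         pair_key(pm$child, pm$parent2)))
  edge_keys <- unique(pair_key(graph$edges$parent, graph$edges$child))
  expect_gte(mean(edge_keys %in% truth_keys), 0.95)
  expect_gte(mean(truth_keys %in% edge_keys), 0.70)
  # exactly two calibration rounds, the second no looser than the first
  expect_false(is.null(graph$thresholds$round2))
  expect_gte(graph$thresholds$round2$k_min, graph$thresholds$round1$k_min)
  expect_gte(graph$thresholds$round1$ibd0_max, 0)
  # identical inputs reproduce the identical graph
  graph2 <- iterate_reconstruction(built$genotypes, known_trios = known,
                                   meta = built$meta)
  expect_identical(graph$edges, graph2$edges)
  expect_identical(graph$trios, graph2$trios)
})

test_that("reconstruction degenerates gracefully without first-degree pairs", {
  fnd <- simulate_founders(20, 1500, seed = 77)
  expect_warning(
    g <- iterate_reconstruction(
      fnd, config = reconstruction_config(k_min = 0.133, ibd0_max = 0.005)),
    "round 2 skipped")
  expect_equal(nrow(g$edges), 0L)
  expect_length(find_founders(g), 0L)
  # no knowns and no fixed thresholds is a configuration error
  expect_error(iterate_reconstruction(fnd), "no known trios")
})
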