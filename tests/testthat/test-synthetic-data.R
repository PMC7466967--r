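test_that("founder simulation is seed-deterministic and respects HWE", {
  a <- simulate_founders(50, 200, seed = 9)
  b <- simulate_founders(50, 200, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_false(identical(unclass(a), unclass(simulate_founders(50, 200, seed = 10))))
  # degenerate range p = 0.5: heterozygote fraction ~ 2pq = 0.5
  g <- simulate_founders(2000, 50, maf_range = c(0.5, 0.5), seed = 11)
  expect_equal(mean(unclass(g) == 1L), 0.5, tolerance = 0.02)
  expect_error(simulate_founders(10, 10, maf_range = c(0.2, 0.1)))
  expect_error(simulate_founders(10, 10, maf_range = c(0, 0.5)))
})

test_that("empirical founder frequencies match an independently simulated draw", {
  # oracle: draw p ~ U(0.05, 0.5) and binomial allele counts directly, then
  # compare the two empirical frequency distributions
  n <- 200; n_snps <- 5000
  gm <- simulate_founders(n, n_snps, maf_range = c(0.05, 0.5), seed = 21)
  phat <- allele_frequencies(gm)
  set.seed(22)
  p <- runif(n_snps, 0.05, 0.5)
  phat_oracle <- rbinom(n_snps, 2L * n, p) / (2 * n)
  ks <- suppressWarnings(ks.test(phat, phat_oracle))
  expect_gt(ks$p.value, 0.001)
})

test_that("offspring follow Mendelian gamete sampling", {
  expect_identical(simulate_offspring(2L, 2L, seed = 1), 2L)
  expect_identical(simulate_offspring(2L, 0L, seed = 1), 1L)
  expect_identical(simulate_offspring(NA_integer_, 2L, seed = 1), NA_integer_)
  expect_error(simulate_offspring(c(1L, 1L), 1L), "length")
  # het x het segregates 1:2:1
  off <- simulate_offspring(rep(1L, 10000), rep(1L, 10000), seed = 23)
  counts <- tabulate(off + 1L, nbins = 3L)
  gof <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("build_pedigree executes the crossing and clone plans with exact truth", {
  plan <- data.frame(parent1 = "FND001", parent2 = "FND002", n_offspring = 3L)
  clones <- data.frame(source = "FND001", n_copies = 2L)
  cfg <- sim_config(n_founders = 2, n_snps = 60, crossing_plan = plan,
                    clone_plan = clones, seed = 3)
  built <- build_pedigree(cfg)
  expect_equal(nrow(built$genotypes), 7L)     # 2 founders + 3 offspring + 2 clones
  expect_equal(nrow(built$truth$parent_map), 3L)
  expect_setequal(built$truth$founders, c("FND001", "FND002"))
  grp <- built$truth$duplicate_groups
  expect_setequal(grp$sample_id[grp$group_id == "FND001"],
                  c("FND001", "FND001_cl1", "FND001_cl2"))
  # clones carry their source's origin year and replicate group
  meta <- built$meta
  rownames(meta) <- meta$sample_id
  expect_equal(meta["FND001_cl1", "origin_year"], meta["FND001", "origin_year"])
  expect_equal(meta["FND001_cl1", "replicate_group"], "FND001")
  # identical seed, identical build
  expect_identical(unclass(build_pedigree(cfg)$genotypes),
                   unclass(built$genotypes))
})

test_that("invalid crossing plans are rejected", {
  bad <- sim_config(2, 10, crossing_plan = data.frame(
    parent1 = "FND001", parent2 = "GHOST", n_offspring = 1L), seed = 1)
  expect_error(build_pedigree(bad), "unknown parent")
  self <- sim_config(2, 10, crossing_plan = data.frame(
    parent1 = "FND001", parent2 = "FND001", n_offspring = 1L), seed = 1)
  expect_error(build_pedigree(self), "self-cross")
})

test_that("error-free pedigrees contain no Mendelian impossibilities", {
  plan <- data.frame(parent1 = c("FND001", "FND003", "OFF001"),
                     parent2 = c("FND002", "FND004", "OFF002"),
                     n_offspring = c(2L, 1L, 2L))
  cfg <- sim_config(4, 800, crossing_plan = plan, seed = 17)
  built <- build_pedigree(cfg)
  res <- trio_error_rates(built$genotypes, stats::setNames(
    built$truth$parent_map, c("offspring", "parent1", "parent2")))
  expect_true(all(res$error_rate == 0))
  # and parent-offspring pairs share an allele everywhere (no opposite homs)
  m <- unclass(built$genotypes)
  pm <- built$truth$parent_map
  for (i in seq_len(nrow(pm))) {
    expect_equal(pair_counts(m[pm$child[i], ], m[pm$parent1[i], ])$n_opp_hom, 0L)
  }
  # clones at zero error are exact copies
  cfgc <- sim_config(2, 300, clone_plan = data.frame(source = "FND002",
                                                     n_copies = 1L), seed = 2)
  b2 <- build_pedigree(cfgc)
  expect_identical(unclass(b2$genotypes)["FND002", ],
                   unclass(b2$genotypes)["FND002_cl1", ])
})

test_that("corruption applies the planted missingness and error rates", {
  gm <- simulate_founders(200, 5000, seed = 31)
  expect_identical(unclass(corrupt(gm, 0, 0, seed = 1)), unclass(gm))
  allmiss <- corrupt(gm[1:5, 1:50], 0, 1, seed = 1)
  expect_true(all(is.na(unclass(allmiss))))
  cr <- corrupt(gm, 0.005, 0, seed = 32)
  changed <- mean(unclass(cr) != unclass(gm))
  expect_lt(abs(changed - 0.005), 5e-4)          # binomial 3-sigma is ~2e-4
  cm <- corrupt(gm, 0, 0.01, seed = 33)
  expect_lt(abs(mean(is.na(unclass(cm))) - 0.01), 5e-4)
  # determinism
  expect_identical(unclass(corrupt(gm, 0.01, 0.01, seed = 7)),
                   unclass(corrupt(gm, 0.01, 0.01, seed = 7)))
})

test_that("the default desk-scale scenario has the documented shape", {
  cfg <- default_sim_config(seed = 4)
  expect_equal(cfg$n_founders, 60L)
  expect_equal(cfg$n_snps, 10000L)
  expect_equal(sum(cfg$crossing_plan$n_offspring), 130L)
  expect_equal(sum(cfg$clone_plan$n_copies), 10L)
  expect_equal(cfg$genotype_error_rate, 0.002)
  expect_equal(cfg$missing_rate, 0.01)
  # three generations: some second-round crosses use F1 parents
  expect_true(any(grepl("^OFF", cfg$crossing_plan$parent1)))
})
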