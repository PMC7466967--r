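test_that("VCF dosage coding follows the alternate-allele-count convention", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t101\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t1|0",
    "1\t202\trs2\tC\tT\t.\t.\t.\tGT\t./.\t1/1",
    "1\t303\t.\tG\tA\t.\t.\t.\tGT\t0|0\t0/0")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_genotypes(path, format = "vcf")
  expect_equal(dim(gm), c(2L, 3L))
  expect_equal(unname(unclass(gm)[, "rs1"]), c(1L, 1L))
  expect_equal(unname(unclass(gm)[, "rs2"]), c(NA_integer_, 2L))
  # ID-less records fall back to chrom_pos ids
  expect_equal(colnames(gm), c("rs1", "rs2", "1_303"))
  expect_equal(unname(unclass(gm)[, "1_303"]), c(0L, 0L))
})

test_that("malformed VCF records are rejected with the record named", {
  base <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(base, "1\t10\tmulti\tA\tG,T\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_genotypes(path, format = "vcf"), "multiallelic.*multi")
  writeLines(c(base, "1\t11\tindel\tAT\tA\t.\t.\t.\tGT\t0/1"), path)
  expect_error(read_genotypes(path, format = "vcf"), "non-SNP.*indel")
  writeLines(c(base, "1\t12\thap\tA\tG\t.\t.\t.\tGT\t0"), path)
  expect_error(read_genotypes(path, format = "vcf"), "non-diploid")
  writeLines(c(base, "1\t13\ttrip\tA\tG\t.\t.\t.\tGT\t0/1/1"), path)
  expect_error(read_genotypes(path, format = "vcf"), "non-diploid")
})

test_that("write-then-read is the identity in both formats", {
  set.seed(5)
  gm <- random_gm(6, 40, miss = 0.15, seed = 5)
  for (fmt in c("table", "vcf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_genotypes(gm, path, format = fmt)
    back <- read_genotypes(path, format = fmt)
    expect_equal(unclass(back)[, ], unclass(gm)[, ], ignore_attr = FALSE)
  }
  # missing renders as the documented sentinel in each dialect
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(genotype_matrix(rbind(a = c(1L, NA))), tpath, "table")
  expect_match(paste(readLines(tpath), collapse = "\n"), "NA")
  vpath <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(genotype_matrix(rbind(a = c(1L, NA))), vpath, "vcf")
  expect_match(paste(readLines(vpath), collapse = "\n"), "\\./\\.")
})

test_that("writing an empty matrix is refused", {
  gm <- genotype_matrix(matrix(integer(0), nrow = 0, ncol = 3,
                               dimnames = list(NULL, c("a", "b", "c"))))
  expect_error(write_genotypes(gm, tempfile(), "table"), "empty")
})

test_that("the genotype table has one row per sample and one column per SNP", {
  gm <- genotype_matrix(rbind(a = c(0L, 1L, 2L), b = c(2L, 2L, 0L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, path, "table")
  lines <- readLines(path)
  expect_length(lines, 3L)                     # header + 2 samples
  expect_length(strsplit(lines[1], "\t")[[1]], 4L)  # id + 3 SNPs
})

test_that("container invariants are enforced", {
  expect_error(genotype_matrix(rbind(a = c(0, 3))), "dosages")
  expect_error(genotype_matrix(rbind(a = 0:1, a = 1:2)), "sample ids")
  m <- matrix(0:1, 2, 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(genotype_matrix(m), "SNP ids")
})

test_that("SNP missingness filter keeps exactly the SNPs at or under threshold", {
  # missing fractions 0.00, 0.01, 0.03 over 100 samples
  m <- matrix(1L, nrow = 100, ncol = 3,
              dimnames = list(sprintf("s%03d", 1:100), c("m0", "m1", "m3")))
  m[1, "m1"] <- NA; m[1:3, "m3"] <- NA
  gm <- genotype_matrix(m)
  kept <- filter_snps_by_missingness(gm, 0.02)
  expect_equal(colnames(kept), c("m0", "m1"))
  expect_equal(nrow(kept), 100L)
  expect_equal(colnames(filter_snps_by_missingness(gm, 1)), colnames(gm))
  full <- genotype_matrix(matrix(1L, 4, 4))
  expect_equal(dim(filter_snps_by_missingness(full, 0)), dim(full))
  expect_error(filter_snps_by_missingness(gm, 1.5))
})

test_that("sample call-rate filter applies the 0.96385 style threshold", {
  m <- matrix(1L, nrow = 2, ncol = 20, dimnames = list(c("hi", "lo"), NULL))
  m[2, 1] <- NA                       # call rates 1.00 and 0.95
  gm <- genotype_matrix(m)
  kept <- filter_samples_by_call_rate(gm, 0.96385)
  expect_equal(rownames(kept), "hi")
  expect_equal(rownames(filter_samples_by_call_rate(gm, 0)), c("hi", "lo"))
  expect_warning(out <- filter_samples_by_call_rate(
    genotype_matrix(rbind(a = c(NA, NA, 1L))), 0.9), "all samples")
  expect_equal(nrow(out), 0L)
})

test_that("QC filters are idempotent, and order-free when nothing sits on a boundary", {
  for (seed in 1:10) {
    gm <- random_gm(12, 30, miss = 0.05, seed = seed)
    f1 <- filter_snps_by_missingness(gm, 0.15)
    expect_identical(unclass(filter_snps_by_missingness(f1, 0.15)), unclass(f1))
    f2 <- filter_samples_by_call_rate(gm, 0.9)
    expect_identical(unclass(filter_samples_by_call_rate(f2, 0.9)), unclass(f2))
  }
  # the two filters interact: removing high-missingness SNPs raises sample
  # call rates, so order can matter.  They provably commute when one of them
  # removes nothing -- e.g. on a fully called matrix, or with a permissive
  # sample threshold.
  full <- genotype_matrix(matrix(rep(0:2, 20), nrow = 5))
  expect_identical(
    unclass(filter_samples_by_call_rate(filter_snps_by_missingness(full, 0.1), 0.9)),
    unclass(filter_snps_by_missingness(filter_samples_by_call_rate(full, 0.9), 0.1)))
  gm <- random_gm(12, 30, miss = 0.05, seed = 99)
  expect_identical(
    unclass(filter_samples_by_call_rate(filter_snps_by_missingness(gm, 0.2), 0)),
    unclass(filter_snps_by_missingness(filter_samples_by_call_rate(gm, 0), 0.2)))
})

test_that("allele frequencies use called samples only and ignore sample order", {
  gm <- genotype_matrix(rbind(a = c(0L, 0L, 2L), b = c(1L, 0L, NA),
                              c = c(2L, 0L, NA)))
  p <- allele_frequencies(gm)
  expect_equal(unname(p), c(0.5, 0, 1))
  shuffled <- gm[c(3, 1, 2), ]
  expect_equal(allele_frequencies(shuffled), p)
  expect_true(all(p >= 0 & p <= 1))
  # zero called samples -> flagged NaN
  gm2 <- genotype_matrix(rbind(a = c(1L, NA), b = c(1L, NA)))
  expect_true(is.nan(allele_frequencies(gm2)[2]))
  qc <- snp_qc_report(gm)
  expect_true(all(qc$maf >= 0 & qc$maf <= 0.5, na.rm = TRUE))
})

test_that("sample metadata and trio lists round-trip with blanks as unknowns", {
  meta <- data.frame(sample_id = c("a", "b"), taxon = c("P. communis", NA),
                     origin_year = c(1850L, NA),
                     replicate_group = c(NA, "grp1"),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, path)
  expect_equal(read_sample_metadata(path), meta)
  trios <- data.frame(offspring = c("x", "y"), parent1 = c("a", "b"),
                      parent2 = c("b", NA), stringsAsFactors = FALSE)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_trio_list(trios, tp)
  expect_equal(read_trio_list(tp), trios)
})
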