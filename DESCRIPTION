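Package: kinped
Title: Kinship-Based Pedigree Reconstruction and Duplicate Detection for
    SNP-Genotyped Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating diploid, biallelic SNP genotype data from
    germplasm repositories: identity-by-state detection of clonal duplicates
    with a replicate-calibrated threshold, KING-robust kinship and zero-IBD
    estimation, Mendelian consistency testing of parent-offspring trios and
    duos, and a two-round parent-offspring pedigree reconstruction with
    quantile-calibrated classification thresholds.  A synthetic-genotype
    generator plants multi-generation pedigrees, clones, genotyping error and
    missingness with full truth tables, so every estimator can be validated by
    parameter recovery.  Pedigrees export to Helium-compatible tables and
    plain edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
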