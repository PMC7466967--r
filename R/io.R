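#' Read a genotype matrix from VCF or a plain genotype table
#'
#' Two on-disk representations are supported.  `"vcf"` consumes diploid,
#' biallelic SNP records (only the GT field is used); phased and unphased
#' calls are accepted and `./.` maps to missing.  `"table"` is a
#' tab-separated file with one row per sample: first column the sample id,
#' header row of SNP ids, cells in `{0, 1, 2, NA}`.
#'
#' @param path input file.
#' @param format `"vcf"`, `"table"`, or `"auto"` (by file extension:
#'   `.vcf`/`.vcf.gz` is VCF, anything else a table).
#' @return a [genotype_matrix()].  For VCF input the CHROM/POS/REF/ALT
#'   columns are carried along as opaque metadata in attribute `snp_info`
#'   (the pipeline treats SNPs as unlinked; positions are 1-based as per the
#'   VCF standard).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "table"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, vcf = read_genotypes_vcf(path), table = read_genotypes_table(path))
}

# GT-string -> dosage lookup covering every legal diploid biallelic call
.gt_codes <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L,
  "./." = NA_integer_, ".|." = NA_integer_, "." = NA_integer_,
  "./0" = NA_integer_, "0/." = NA_integer_, "./1" = NA_integer_,
  "1/." = NA_integer_, ".|0" = NA_integer_, "0|." = NA_integer_,
  ".|1" = NA_integer_, "1|." = NA_integer_
)

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  rec_label <- function(i) {
    sprintf("%s:%s (%s)", fix[i, "CHROM"], fix[i, "POS"],
            ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]))
  }
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    stop("multiallelic (or ALT-less) record: ", rec_label(which(multi)[1]))
  }
  not_snp <- nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(not_snp)) {
    stop("non-SNP record: ", rec_label(which(not_snp)[1]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  d <- .gt_codes[gt]
  bad <- !is.na(gt) & !(gt %in% names(.gt_codes))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-diploid or multiallelic genotype '", gt[bad][1],
         "' at record ", rec_label(idx[1]),
         ", sample ", colnames(gt)[idx[2]])
  }
  d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  fallback <- is.na(ids) | ids == "."
  ids[fallback] <- paste(fix[fallback, "CHROM"], fix[fallback, "POS"], sep = "_")
  gm <- genotype_matrix(t(d), snp_ids = ids)
  attr(gm, "snp_info") <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  gm
}

read_genotypes_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop("genotype table needs a sample-id column plus SNPs")
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  genotype_matrix(m, sample_ids = ids)
}

#' Write a genotype matrix to VCF or a plain genotype table
#'
#' The output re-reads with [read_genotypes()] into an identical matrix.
#' Missing calls render as `./.` (VCF) or `NA` (table).  The VCF writer
#' emits plain (uncompressed) VCF v4.2 text so outputs stay diffable; when
#' the matrix came from a VCF its `snp_info` metadata (CHROM/POS/REF/ALT) is
#' reproduced, otherwise placeholder coordinates are generated.
#'
#' @param gm genotype matrix (non-empty; writing an empty matrix is refused).
#' @param path output file.
#' @param format `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("table", "vcf")) {
  format <- match.arg(format)
  validate_genotype_matrix(gm)
  if (nrow(gm) == 0L || ncol(gm) == 0L) {
    stop("refusing to write an empty genotype matrix")
  }
  switch(format,
         table = write_genotypes_table(gm, path),
         vcf = write_genotypes_vcf(gm, path))
  invisible(path)
}

write_genotypes_table <- function(gm, path) {
  dt <- data.table::data.table(sample_id = rownames(gm))
  dt <- cbind(dt, data.table::as.data.table(unclass(gm)))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
}

write_genotypes_vcf <- function(gm, path) {
  m <- unclass(gm)
  info <- attr(gm, "snp_info")
  if (is.null(info) || nrow(info) != ncol(m)) {
    info <- data.frame(chrom = "1", pos = seq_len(ncol(m)), id = colnames(m),
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  gt_str <- c("0/0", "0/1", "1/1")
  cells <- matrix("./.", nrow = ncol(m), ncol = nrow(m))
  called <- !is.na(t(m))
  cells[called] <- gt_str[t(m)[called] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kinped",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t"))
  body <- paste(info$chrom, info$pos, info$id, info$ref, info$alt,
                ".", ".", ".", "GT",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  # one-sample edge case: apply() collapses correctly above either way
  writeLines(c(header, body), path)
}

#' Read or write sample metadata
#'
#' Tab-separated columns `sample_id`, `taxon`, `origin_year`,
#' `replicate_group`; empty cells mean unknown.  `origin_year`, when
#' present, must be a plausible calendar year.
#'
#' @param path file path.
#' @return data frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                          colClasses = list(character = "sample_id"))
  need <- c("sample_id", "taxon", "origin_year", "replicate_group")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  meta <- as.data.frame(dt[, need, with = FALSE])
  meta$origin_year <- as.integer(meta$origin_year)
  bad <- !is.na(meta$origin_year) & (meta$origin_year < 1000L | meta$origin_year > 2100L)
  if (any(bad)) stop("implausible origin_year for sample ", meta$sample_id[bad][1])
  meta
}

#' @rdname read_sample_metadata
#' @param meta sample metadata data frame.
#' @export
write_sample_metadata <- function(meta, path) {
  data.table::fwrite(meta, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read or write a trio/duo list
#'
#' Tab-separated columns `offspring`, `parent1`, `parent2`; an empty
#' `parent2` denotes a duo (single known parent).
#'
#' @param path file path.
#' @return data frame with columns offspring, parent1, parent2.
#' @export
read_trio_list <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                          colClasses = "character")
  need <- c("offspring", "parent1")
  if (!all(need %in% names(dt))) stop("trio list needs offspring and parent1 columns")
  if (!"parent2" %in% names(dt)) dt$parent2 <- NA_character_
  as.data.frame(dt[, c("offspring", "parent1", "parent2"), with = FALSE])
}

#' @rdname read_trio_list
#' @param trios trio data frame.
#' @export
write_trio_list <- function(trios, path) {
  data.table::fwrite(trios[, c("offspring", "parent1", "parent2")], path,
                     sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Write or read simulation truth tables
#'
#' The planted truth of a synthetic run: the parent map (`child`, `parent1`,
#' `parent2`) and the duplicate partition (`sample_id`, `group_id`), as two
#' tab-separated files in `dir`.  The founder set is derivable (samples that
#' never appear as a child).
#'
#' @param truth a `truth_tables` list from [build_pedigree()].
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `truth_tables` list (read).
#' @export
write_truth_tables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(truth$parent_map, file.path(dir, "parent_map.tsv"),
                     sep = "\t", na = "", quote = FALSE)
  data.table::fwrite(truth$duplicate_groups, file.path(dir, "duplicates.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}

#' @rdname write_truth_tables
#' @export
read_truth_tables <- function(dir) {
  pm <- as.data.frame(data.table::fread(file.path(dir, "parent_map.tsv"),
                                        sep = "\t", na.strings = c("", "NA"),
                                        colClasses = "character"))
  dg <- as.data.frame(data.table::fread(file.path(dir, "duplicates.tsv"),
                                        sep = "\t", colClasses = "character"))
  founders <- setdiff(unique(c(pm$parent1, pm$parent2)), pm$child)
  structure(list(parent_map = pm, duplicate_groups = dg,
                 founders = founders[!is.na(founders)]),
            class = "truth_tables")
}
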