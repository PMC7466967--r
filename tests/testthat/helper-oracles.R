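# Brute-force oracles, deliberately independent of the package's vectorized
# implementations: they loop over SNPs (or enumerate gametes) one at a time.

# enumerate one allele from each parent and ask whether any sum matches
oracle_trio_status <- function(p1, p2, ch) {
  if (any(is.na(c(p1, p2, ch)))) return("untestable")
  alleles <- function(d) list(c(0L, 0L), c(0L, 1L), c(1L, 1L))[[d + 1L]]
  sums <- outer(alleles(p1), alleles(p2), `+`)
  if (ch %in% sums) "consistent" else "inconsistent"
}

oracle_pair_counts <- function(a, b) {
  out <- list(n_het_het = 0L, n_opp_hom = 0L, n_het_a = 0L, n_het_b = 0L,
              n_valid = 0L)
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    out$n_valid <- out$n_valid + 1L
    if (a[i] == 1L) out$n_het_a <- out$n_het_a + 1L
    if (b[i] == 1L) out$n_het_b <- out$n_het_b + 1L
    if (a[i] == 1L && b[i] == 1L) out$n_het_het <- out$n_het_het + 1L
    if (abs(a[i] - b[i]) == 2L) out$n_opp_hom <- out$n_opp_hom + 1L
  }
  out
}

oracle_ibs <- function(a, b) {
  s <- 0; n <- 0L
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    s <- s + (2 - abs(a[i] - b[i])) / 2
    n <- n + 1L
  }
  if (n == 0L) NA_real_ else unname(s / n)
}

# small random genotype matrix with missingness
random_gm <- function(n_samples, n_snps, miss = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
              nrow = n_samples)
  m[matrix(runif(length(m)) < miss, nrow = n_samples)] <- NA_integer_
  genotype_matrix(m, sample_ids = sprintf("S%02d", seq_len(n_samples)))
}
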