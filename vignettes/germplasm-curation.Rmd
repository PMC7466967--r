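---
title: "Curating SNP-genotyped germplasm: duplicates, kinship and pedigree reconstruction"
author: "kinped authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating SNP-genotyped germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

Clonally propagated crop collections carry two kinds of hidden structure
that genotyping exposes. First, many accessions are the *same* genotype:
propagation copies, somatic sports, synonyms acquired across centuries of
exchange, and plain labeling errors. Second, the *documented* parentages of
cultivars are frequently incomplete or wrong, while the true parent–offspring
structure is recoverable from the genotypes themselves. `kinped` implements
both analyses for diploid, biallelic SNP data — duplicate detection by
identity-by-state, and pedigree reconstruction from KING-robust kinship with
Mendelian confirmation — together with a synthetic-data generator that
plants a known pedigree so every estimator can be checked by parameter
recovery.

# Data model

The universal currency is a samples × SNPs matrix of alternate-allele
dosages 0/1/2 with `NA` for missing calls (`genotype_matrix()`). VCF (GT
field only, diploid biallelic records) and a tab-separated genotype table
are read and written losslessly; SNP coordinates, where present, are carried
as opaque metadata because every method here treats loci as exchangeable and
unlinked. Sample metadata (taxon, origin year, replicate group) joins by
sample id and is used only where stated below.

Quality control mirrors standard array practice: per-sample call-rate
filtering (default ≥ 0.96385), per-SNP missingness filtering (default:
remove above 2%), and a per-SNP Mendelian-error filter over known trios
(default: remove above 5%). The two marginal filters are each idempotent,
but they interact — removing high-missingness SNPs raises sample call
rates — so the pipeline applies them in one fixed order (sample call rate →
duplicate collapse → SNP missingness → SNP Mendelian error) rather than
pretending the order is immaterial.

# Duplicate detection

IBS between two samples is the mean of `(2 − |d₁ − d₂|)/2` over SNPs called
in both. Clones differ only through genotyping error, so their IBS sits just
under 1; the decision threshold is taken as the *minimum* IBS among declared
biological/technical replicate pairs — the most conservative value that
still unites everything known to be identical — with 0.977 as the default
when no replicates are available. A replicate pair scoring implausibly low
(< 0.95) still sets the threshold but triggers a loud warning, because a
mislabeled "replicate" is the more likely explanation.

Groups are connected components of the thresholded IBS graph
(single-linkage), since "is the same genotype as" is treated as transitive
in curation practice. The known cost is chaining: a borderline pair can
merge two otherwise-distinct groups. Each group is represented downstream by
its member with the fewest missing calls (ties break to the
lexicographically smallest id, so runs are reproducible).

# Relatedness estimation

For a pair, over jointly called SNPs, with `N_Aa,Aa` the both-heterozygous
count, `N_AA,aa` the opposite-homozygote count and `N_Aa^(i)` each sample's
heterozygous count:

$$\hat k \;=\; \frac{N_{Aa,Aa} - 2\,N_{AA,aa}}{N_{Aa}^{(1)} + N_{Aa}^{(2)}}$$

This moment estimator of the kinship coefficient is robust to population
structure and requires no LD pruning; it recovers 0.5 for clones, 0.25 for
parent–offspring (PO) and full-sib (FS) pairs, and 0 for unrelated pairs.
The KING family also contains a `2·min(N_Aa^(1), N_Aa^(2))` denominator
variant; both recover 0.25 for first-degree pairs under Hardy–Weinberg, the
sum form is the default, and the min form sits behind
`king_kinship(..., denominator = "min")`.

PO and FS are separated by zero-IBD sharing. The raw signal is the
opposite-homozygote fraction `ibs0 = N_AA,aa / N_valid` — exactly zero for an
error-free PO pair, since a parent always transmits one allele. To put it on
the IBD0 probability scale it is divided by the expected unrelated rate
under HWE, the mean of `2p²(1−p)²` over the same SNPs, using allele
frequencies computed from the analyzed (post-deduplication) sample set
itself — no external reference panel is assumed. The normalized statistic
sits near 0 for PO, 0.25 for FS, and 1 for unrelated pairs. Both forms are
always reported; classification uses the normalized one by default. Note
that under genotyping error the *normalized* statistic inflates by roughly
`error-rate / mean(2p²q²)`, an order of magnitude above the raw fraction —
one reason the classification thresholds are calibrated from data rather
than fixed at theoretical values.

Pairs sharing fewer than 100 called SNPs (configurable) are reported but
flagged undefined instead of estimated: a kinship value from a handful of
SNPs is noise with a confident-looking sign.

# Mendelian testing

A fully called (parent, parent, offspring) dosage triple is consistent when
one allele from each parent can sum to the offspring dosage. Because the
transmissible allele set of each dosage is an interval, the test reduces to
`lo₁ + lo₂ ≤ d_child ≤ hi₁ + hi₂` with `lo = [dosage = 2]`,
`hi = [dosage ≥ 1]`; 12 of the 27 combinations are inconsistent, and the
implementation is checked against exhaustive gamete enumeration in the test
suite. Error rates use *testable* SNPs (called in all three samples) as the
denominator, so missingness does not dilute them. Duos — a single candidate
parent — expose only one Mendelian impossibility, the opposite homozygote,
so the duo error rate is that fraction, held to the same 1.5% confirmation
ceiling as trios. Trios containing two copies of the same sample id are
rejected outright; a clone always "passes" a trio test vacuously.

# Two-round pedigree reconstruction

Theoretical thresholds (k = 0.25, IBD0 = 0) are never attained in practice;
the procedure instead calibrates decision bounds from parentages that are
already known and Mendelian-verified (error ≤ 10%):

* `k_min` — the nearest-rank `(1−q)` quantile of the known PO pairs'
  kinship values: the largest bound that keeps a fraction `q` of known pairs
  at or above it;
* `ibd0_max` — the nearest-rank `q` quantile of their zero-IBD values.

Round 1 uses `q = 0.90`. All pairs with `k ≥ k_min` are first-degree; of
those, `ibd0 ≤ ibd0_max` means PO, otherwise FS. For each sample, every
unordered pair of its PO partners is trio-tested, trios below 1.5% Mendelian
error are confirmed (lowest error wins; alternates are counted rather than
silently dropped), and PO pairs not covered by a confirmed trio are
confirmed as duos by the opposite-homozygote ceiling. Round 2 recalibrates
at `q = 0.95` from the newly confirmed pairs and repeats classification and
confirmation over *all* pairs; exactly two rounds are run, and the union of
confirmed relationships (with at most one confirmed parent pair per
offspring — earliest round, then lowest error) forms the pedigree. Known
parentages that pass the 1.5% ceiling themselves enter the graph as round 0.

FS calls are retained as annotations but never create parent edges. Trio
edges are directed parent→offspring by construction; duo edges are directed
old→young only when both accessions carry documented origin years and the
years differ (equal or missing years leave the edge undirected and
flagged, and an orientation that would give a child a third parent is
refused). Founders are nodes with confirmed offspring and no confirmed
parent. The directed graph must be acyclic — a cycle means the input was not
deduplicated or a confirmation is wrong, and it is a hard error rather than
a warning. Export formats are the three-column individual/parent1/parent2
table consumed by Helium and a flat edge list with supporting statistics.

## What the calibration buys — and what it costs

Calibrating to the data absorbs genotyping error, inbreeding and structure
without manual tuning. The cost is intrinsic: a threshold placed at the
`q`-coverage quantile of known pairs excludes, in expectation, a fraction
`1−q` of *all* true pairs per gate (known and unknown pairs are
exchangeable). With two gates at `q = 0.90` the joint retention of true PO
pairs is bounded near 0.81–0.90 (the two gate failures are positively
correlated through the shared opposite-homozygote count), and the round-2
recalibration — computed from pairs that already passed round 1, i.e. a
left-truncated sample — can only tighten the bounds. On the default
desk-scale scenario this yields pair recall ≈ 0.87 and trio recall ≈ 0.75 at
precision 1.0 (see `evaluation.json` of a default run and the acceptance
test). Users who need recall above that ceiling must either raise `q`
(admitting more false positives past the k gate) or supply fixed thresholds
(`k_min`, `ibd0_max`) from external knowledge; fixed values in the region of
0.133/0.005, typical for well-QCed array data, behave that way when marker
error is very low.

A second, small-data effect: with only 1–2k SNPs, a PO pair's
opposite-homozygote count is a small integer, the known-pair quantile of the
zero-IBD statistic collapses to 0, and any pair with a single opposite
homozygote fails the PO gate. The validation scenarios therefore use 10k
SNPs, the scale the procedure is designed for.

# The synthetic-data generator

`build_pedigree()` executes a declarative scenario: founders drawn under
HWE with per-SNP allele frequencies uniform on a MAF range (default
0.05–0.5), an ordered crossing plan (later crosses may use earlier
offspring, giving multi-generation pedigrees and, through shared ancestors,
inbreeding), clonal copies, and finally per-genotype corruption — missing
with probability `missing_rate`, otherwise replaced by one of the two other
dosages with probability `genotype_error_rate`. Truth tables record the
exact parent map, duplicate partition and founder set; metadata assigns
origin years stratified by generation so duo orientation is exercisable.

The default desk-scale scenario is 200 samples (60 founders; 40 founder
crosses × 2 offspring; 25 second-round crosses × 2, drawing mostly F1
parents; 10 clonal copies over 6 sources, one source with 3 copies to mimic
a heavily duplicated heritage cultivar), 10,000 unlinked SNPs, error 0.002,
missingness 0.01 — sizes chosen so a full pipeline run with evaluation
completes in well under a minute while keeping the kinship sampling error
(~0.005) far below the PO/FS separation. Validation cohorts (50 PO pairs,
50 FS pairs, 20 clones, 30 trios, each at 10k SNPs) match the scales used
in the acceptance script.

What the generator deliberately does **not** emulate: linkage and
recombination maps (the estimators assume exchangeable unlinked loci — real
arrays are LD-pruned or simply dense enough that this is a second-order
effect for KING-robust), population structure and admixture (KING-robust is
chosen for robustness to it, but the simulations do not stress it),
selfing and self-incompatibility, null alleles or allele-specific error,
and polyploidy. Passing the recovery tests therefore demonstrates
correctness of the estimators and the procedure under the model's
assumptions, not performance on a structured real collection.

# Numerical and design choices

* Nearest-rank quantiles (`ceiling(q·n)`-th order statistic, clamped to
  `[1, n]`) — exact, distribution-free, and degenerate cases (`q = 1`) give
  the min/max as intended.
* Strict inequality at the confirmation ceiling (`error < 1.5%`),
  inclusive elsewhere (`k ≥ k_min`, `ibd0 ≤ ibd0_max`, filters keep
  "at most" / "at least" their thresholds).
* Ties: duplicate-group representatives break ties lexicographically;
  equal-error parent pairs resolve by parent-id order; group ids are the
  lexicographically smallest member.
* Degenerate inputs: pairs with no shared called SNPs, zero-heterozygosity
  kinship denominators, all-monomorphic normalizers and no-testable-SNP
  trios are all reported as flagged `NA`, never silently dropped or zeroed.
* Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; a pipeline run writes a hash manifest, and identical
  config + seed reproduces byte-identical outputs.
* Reversed trios (offspring posing as parent) are not special-cased: they
  fail the Mendelian ceiling numerically (a het offspring with two
  homozygous-reference "parents" occurs at a few percent of SNPs for such
  triples, an order of magnitude above the ceiling).

# Known limitations

* Recall is capped by the coverage quantiles, as analyzed above; this is a
  property of the procedure, not of the implementation.
* Grandparent–grandchild and avuncular pairs (k ≈ 0.125) are safely below
  calibrated k thresholds in the simulated regime, but in noisy or inbred
  real data they can leak into the first-degree band; no additional
  disambiguation is attempted.
* Single-linkage duplicate grouping can chain borderline pairs.
* Duos are confirmable only through the opposite-homozygote rate, which is
  also ~0 for clones and near-clones; duplicate collapse must precede
  reconstruction (the acyclicity check makes violations loud).
* The IBD0 normalization assumes HWE allele frequencies estimated from the
  analyzed set; strong structure biases the normalizer (the raw fraction is
  reported for exactly this reason).
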