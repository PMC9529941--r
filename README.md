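# hadalvirome

Post-assembly viromics for deep-sea sediment metagenomes: rule-based viral
contig curation, species/genus clustering, taxonomy, virus–host linkage,
community ecology and auxiliary-metabolic-gene (AMG) screening — with a
ground-truthed synthetic-data generator so every stage is testable without
any raw sequencing data.

## Who this is for

Microbial ecologists working with sediment (or other environmental)
metagenome assemblies who have already run the standard upstream tools —
assembler, phage predictors, gene annotation, read mapping — and need the
downstream inference layer: which contigs are credibly viral, how they
collapse into viral species (vOTUs) and genera, which prokaryotes they
infect, how the viral community is structured across sites, and which
host-derived metabolic genes the viruses carry.

## The methods at its core

* **Triage.** A predictor-flagged contig is retained iff it has ≥ 2
  viral-specific genes (hallmark keywords: capsid, phage, terminase,
  portal, holin, …), or ≥ 70% unknown/hypothetical genes plus predictor
  support; carries no prokaryote marker gene (e.g. ribosomal proteins);
  and has a conservative signal (determined completeness, a viral gene, or
  a call from a benchmarked tool subset). Contigs recruiting ≥ 1 read from
  blank controls are removed as contaminants. Genome quality tiers:
  *complete* (100% completeness + direct terminal repeat), *high* (>90%),
  *medium* (50–90%), *low* (<50%), *undetermined*.
* **vOTU clustering.** Greedy, longest-first clustering at
  ANI ≥ 95% over ≥ 85% of the shorter contig (AF), with fragment-based ANI
  (500 nt fragments, exact 16-mer seeding on long subjects, per-fragment
  80% identity floor).
* **Genus clustering.** Gene-sharing network: genomes sharing `c` of their
  `a`, `b` protein clusters (universe `M`) are joined when the
  Bonferroni-corrected hypergeometric tail
  `P(X ≥ c) = Σᵢ C(b,i)·C(M−b,a−i)/C(M,a)` gives
  `−log₁₀(P·n_pairs) ≥ 1`; genera are connected components.
* **Taxonomy.** Majority rules: a vOTU gets the unique family collecting
  best-hit votes (bitscore ≥ 50; fallback pass: identity ≥ 50%) from ≥ 50%
  of its proteins.
* **Host linkage.** Four evidence channels — nucleotide homology
  (≥ 2500 nt, ≥ 70% identity, < 90% host coverage), CRISPR spacers
  (full-length, ≤ 1 mismatch, either strand), exact shared tRNAs, and
  order-k Markov genome-composition scoring — integrated into a confidence
  score; predictions with score ≥ 3 are high-confidence.
* **Ecology.** Read filters (identity ≥ 95%, aligned ≥ 50 nt), zero depth
  below 10% covered fraction, normalization per gigabase sequenced,
  pseudo-counts `⌈10 × coverage⌉` for Chao1/ACE, Shannon and inverse
  Simpson on relative abundances, Bray–Curtis PCoA, PERMANOVA
  (p = (1 + #{F* ≥ F}) / (1 + n_perm)), classic t and Wilcoxon group tests,
  and a transcription flag (active: ≥ 20% of genes mapped by > 1
  metatranscriptome read).
* **AMG screening.** Candidates are removed for T/B flags, auxiliary score
  > 3, absence from the curated function list, or failing the positional
  viral-context check (strict mode: a viral-specific gene on each side).

## Worked example

Simulate an annotated assembly, triage it, decontaminate, cluster into
vOTUs, and compare slope vs bottom-axis communities:

```r
library(hadalvirome)
library(dplyr)

gs <- sim_genomes(n_viral = 12, n_host = 4, n_nonviral = 6,
                  sensitivity = 1, specificity = 1, seed = 7)
set.seed(1)
comp <- tibble::tibble(contig_id = gs$truth$contig_id,
                       completeness = round(runif(18, 20, 100)))
dec <- triage_contigs(gs$genes, gs$predictor_calls, comp,
                      contig_ids = gs$truth$contig_id)
count(dec, retained)
#> # A tibble: 2 × 2
#>   retained     n
#>   <lgl>    <int>
#> 1 FALSE        6
#> 2 TRUE        12
```

All 12 planted viral genomes survive triage and the 6 cellular contigs
(ribosomal markers) are rejected. One contig recruits blank-control reads
and is removed before clustering:

```r
keep <- decontaminate(dec$contig_id[dec$retained],
                      tibble::tibble(contig_id = "virus_003", blank_reads = 2L))
keep$removed
#> [1] "virus_003"

votus <- cluster_votus(filter(gs$contigs, contig_id %in% keep$kept))
head(votus, 4)
#> # A tibble: 4 × 5
#>   votu_id   contig_id representative   ani    af
#>   <chr>     <chr>     <lgl>          <dbl> <dbl>
#> 1 vOTU_0001 virus_001 TRUE             100     1
#> 2 vOTU_0002 virus_008 TRUE             100     1
#> 3 vOTU_0003 virus_006 TRUE             100     1
#> 4 vOTU_0004 virus_010 TRUE             100     1
```

Unrelated genomes stay singleton vOTUs (ANI/AF are reported against each
cluster's representative). Community structure across a two-group design
with a planted bottom-axis effect:

```r
cm <- sim_communities(n_votus = 60, n_slope = 8, n_bottom = 8, seed = 11)
ab <- normalize_abundance(zero_low_coverage(cm$depths), cm$sample_gb)
gt <- group_tests(ab, cm$groups, n_perm = 999, seed = 12)
gt
#> Viral community group comparison
#>   PERMANOVA (Bray-Curtis): F = 10.388, p = 0.001
#>   alpha-diversity tests (two-sided):
#>     observed     t p = 6.536e-05, Wilcoxon p = 0.001522
#>     chao1        t p = 0.02128, Wilcoxon p = 0.02813
#>     ace          t p = 0.001782, Wilcoxon p = 0.001088
#>     shannon      t p = 9.782e-05, Wilcoxon p = 0.0001554
#>     inv_simpson  t p = 2.034e-05, Wilcoxon p = 0.0001554
```

The PERMANOVA p of 0.001 is the smallest attainable value at 999
permutations — the planted group effect separates the communities
completely — and every alpha-diversity index differs between the groups.
`tidy(gt)` and `glance(gt)` return the same results as tibbles;
`autoplot(beta_ordination(ab), cm$groups)` draws the ordination.

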