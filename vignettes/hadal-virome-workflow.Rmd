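---
title: "Curating and analysing sediment virome assemblies with hadalvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and analysing sediment virome assemblies with hadalvirome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadalvirome)
library(dplyr)
```

## Scope and model of the data

`hadalvirome` implements the post-assembly inference layer of a sediment
virome survey: everything between an assembled metagenome (plus the outputs
of standard annotation and read-mapping tools) and the community-level
conclusions. The heavy upstream steps — read QC, assembly, the phage
prediction tools themselves, HMM annotation, completeness estimation — are
*inputs*, consumed as plain tables. What the package owns are the decision
rules layered on those inputs:

1. **Triage** of predictor-flagged contigs into high-confidence viral
   contigs, using gene-product keywords, an unknown-gene quorum, a
   prokaryote-marker veto, a conservative-signal requirement, and
   blank-control decontamination.
2. **Species clustering** of the survivors into vOTUs at 95% average
   nucleotide identity over at least 85% of the shorter contig, and
   **genus clustering** through a gene-sharing network.
3. **Taxonomy** by a majority vote of per-protein database hits.
4. **Virus–host linkage** from four independent evidence channels with an
   integrated confidence score.
5. **Ecology**: coverage-based abundance with strict read filters,
   per-gigabase normalization, alpha/beta diversity, ordination and
   permutation tests, and a metatranscriptomic activity flag.
6. **AMG screening** with positional verification of the viral context.

Because the original deep-sea data cannot be reprocessed at desk scale, the
package ships a first-class synthetic-data module (`sim_genomes()`,
`sim_variant()`, `sim_communities()`, `sim_amg_table()`) that generates
ground-truthed inputs with the statistical structure each stage assumes.
Every planted feature (spacer, tRNA, homologous segment, terminal repeat,
group effect, intended AMG verdict) is recorded in truth tables and
recoverable from the emitted records by exact search, which is the backbone
of the test suite.

## Triage rules and their boundaries

A contig reaches triage only if at least one phage-prediction tool flagged
it and it passed the assembly admission filter (`read_contigs()`, strictly
greater than 10,000 nt by default: a 10,000 nt contig is excluded, a
10,001 nt contig admitted).

`classify_gene_product()` buckets each gene annotation into
`viral_specific` (a hallmark keyword from `viral_keywords` — capsid, phage,
terminase, portal, holin, … — matched case-insensitively on word
boundaries, so "head" never fires inside "overhead"), `unknown`
(hypothetical/unknown-function/bare "Viruses" annotations),
`prokaryote_specific` (default pattern: "ribosomal protein"), or `other`.
Precedence is prokaryote > viral > unknown: a contig claiming to be both is
treated as cellular.

`triage_contigs()` then retains a contig iff

* it has ≥ 2 viral-specific genes, **or** ≥ 70% of its genes are
  unknown-type *and* at least one predictor called it; and
* it has no prokaryote-specific gene; and
* a conservative signal exists: completeness was determined, or a
  viral-specific gene is present, or a call came from the benchmarked
  conservative tool subset (DeepVirFinder, VirSorter, VirSorter2, MARVEL,
  VIBRANT by default).

The second retain route's "contained viral sequences" condition is
operationalized as "≥ 1 predictor call", the most literal reading
available; it is configurable only through the predictor-call table a user
supplies. All thresholds surface in `virome_config()` with their default
values.

Quality tiers partition every (completeness, DTR) pair: `complete` requires
100% completeness *and* a direct terminal repeat (detected by
`detect_dtr()` as an exact prefix/suffix overlap of ≥ 20 nt); `high` is
> 90% (strict), `medium` 50–90% (both ends inclusive), `low` < 50%,
`undetermined` when completeness is not estimable. Decontamination removes
any retained contig with ≥ 1 mapped blank-control read — deliberately
aggressive, since a single read in a negative control is already evidence
of library cross-talk.

## Species and genus clustering

`pairwise_ani()` estimates ANI fastANI-style: the shorter sequence is cut
into non-overlapping 500 nt fragments, each aligned to its best window in
the longer sequence (global in the fragment, local in the subject); a
trailing sliver shorter than half a fragment is folded into its
predecessor so that a self-comparison always yields AF = 1. Against
subjects longer than 6 kb, fragments are first placed by exact 16-mer
seeding on the best-supported diagonal; a clean diagonal is scored by
direct per-position comparison (exact when no indels are present), and
placements below the 80% floor or off the diagonal fall back to full
dynamic-programming alignment of the padded window. A fragment with no
conserved 16-mer in the subject counts as unaligned — with dozens of
overlapping probes per fragment this is only likely for fragments already
far below the identity floor. Fragments
reaching 80% identity count as aligned; ANI is the length-weighted mean
identity of aligned fragments, AF their summed length over the shorter
sequence. `N` bases never match anything, a deliberately conservative
choice. A fragment size of 500 nt limits AF resolution to
`fragment / length` of the shorter contig; analyses that need finer AF
granularity on short test sequences can lower `fragment` (the recovery
tests use 100 nt on 4 kb sequences for exactly this reason).

`cluster_votus()` is longest-first greedy clustering: contigs sorted by
length descending (ties broken by id), each joining the first cluster
whose *representative* it matches at ANI ≥ 95 and AF ≥ 0.85, else founding
its own. Representatives are therefore always the longest member, the
result is independent of input order, and every member provably satisfies
the thresholds against its representative (asserted on every run).

Genus-level structure uses a gene-sharing network: for genomes holding `a`
and `b` protein clusters (PCs) of a universe of `M`, sharing `c`, the edge
weight is the hypergeometric tail probability of sharing at least `c` under
random draws, Bonferroni-corrected over all genome pairs and expressed as
`-log10`; edges with score ≥ 1 are kept and genera are the connected
components of that graph. This is a deliberate simplification of the
published gene-sharing tools (which use ClusterONE/MCL); only the decision
structure — "do these genomes share significantly many PCs?" — is under
test here, and the hypergeometric tail is checked against exact enumeration
in the test suite. Whether singleton genomes count as genera is a config
flag (default: they do; both counts are attached to the result).

## Taxonomy

`assign_family()` gives each protein one vote — its best database hit,
qualifying at bitscore ≥ 50 in the primary pass or ≥ 50% identity in the
fallback pass — and assigns the unique family collecting votes from ≥ 50%
of the vOTU's proteins (inclusive). A two-family tie at the threshold
leaves the vOTU unclassified, because a "majority" must be unique. The
fallback pass runs only for vOTUs the primary pass left unassigned. The
fallback criterion is genuinely ambiguous in the source workflows (50%
identity per protein vs a 50% voting fraction); this implementation applies
both readings simultaneously — identity qualifies a protein, the voting
fraction assigns the family.

## Virus–host linkage

Four collectors emit evidence rows; each row re-validates against its own
acceptance rule, so the collectors are idempotent filters:

* **Homology** (`filter_homology_matches()`): alignment ≥ 2500 nt at
  ≥ 70% identity, with total aligned host bases below 90% of the host
  sequence — near-complete coverage indicates a mis-binned viral contig
  rather than an integrated prophage.
* **CRISPR** (`detect_crispr_arrays()` + `match_spacers()`): arrays are
  maximal runs of ≥ 3 exact repeat copies (repeat 23–47 nt, spacers
  26–50 nt, mutually distinct); a spacer links host to virus when it (or
  its reverse complement) occurs at full length with ≤ 1 substitution.
  The published workflows phrase the match tolerance as a BLAST E-value
  cutoff; a full-length ≤ 1-mismatch rule on ≥ 20 nt spacers is strictly
  more conservative and, unlike an E-value, independent of database size.
* **tRNA** (`match_trna()`): only exact full-length matches, either strand.
* **Composition** (`train_markov_models()` + `markov_score()`): order-k
  Markov models (default k = 3, configurable to 7) of each host genome and
  its reverse complement with add-one pseudocounts; a contig is scored by
  mean log-probability per transition and the top-ranked host becomes
  k-mer evidence. k = 3 keeps estimation stable on the ~0.1 Mb synthetic
  hosts used throughout the tests; real MAGs support higher orders.

`integrate_host_evidence()` scores each (virus, host) pair: exact CRISPR
spacer 5, 1-mismatch CRISPR 3, homology 3, tRNA 2, top-rank composition 1;
the pair takes its maximum base value plus 0.5 per additional distinct
method, capped at 5, and predictions with score ≥ 3 are high-confidence.
The published confidence scorer does not print its point table; this one is
a declared surrogate preserving only the published decision boundary
(≥ 3), and changing it is a config override, not a code edit. Composition
evidence alone (1 point) can never reach high confidence — by design, since
k-mer similarity is the weakest channel.

## Ecology

`compute_depth()` admits reads at ≥ 95% identity and ≥ 50 nt aligned, and
reports zero depth for any contig covered over less than 10% of its
positions — the coverage-rate rule that suppresses spurious
single-hotspot recruitment. Both mean and trimmed-mean (default trim 5%
per tail, configurable; used for host genomes) per-base summaries are
available. Normalized coverage is depth per gigabase of sample sequencing;
relative abundances divide by the per-sample total; pseudo-counts are
`ceiling(10 × normalized)` and feed *only* the rare-frequency richness
estimators (Chao1, ACE), while Shannon and inverse Simpson use relative
abundances directly — the integerization exists to give the frequency-based
estimators their singleton/doubleton structure, not to rescale evenness.

Alpha diversity uses the bias-corrected Chao1
(`S + F1(F1−1)/(2(F2+1))`, finite even when no doubletons exist) and ACE
with the standard rare cutoff of 10; when nothing is rare, ACE degenerates
to observed richness, and when every rare species is a singleton (sample
coverage zero) it falls back to Chao1. Shannon uses the natural log (the
base is not fixed by convention; natural log is vegan's default and is
what the cross-check tests assert against). Bray–Curtis distances and
PERMANOVA go through vegan (`vegdist`, `adonis2`, free permutations, 999
by default — making the smallest attainable p 0.001); PCoA is the
classical double-centered eigendecomposition with coordinates scaled by
the square root of each positive eigenvalue, negative-eigenvalue axes
reported and dropped. Group comparisons add classic equal-variance
two-sided t tests and two-sided Wilcoxon rank-sum tests (exact null for
groups of ≤ 10) per alpha index; results carry `tidy()`/`glance()`
methods.

A vOTU is transcriptionally *active* when ≥ 20% of its genes are mapped by
more than one metatranscriptome read. ">1 read" is implemented strictly
(≥ 2): one read is compatible with index hopping, two are not.

## AMG screening

`filter_amg_candidates()` removes a candidate when (in order) it carries a
T or B flag, its auxiliary score exceeds 3, its function is absent from the
user-supplied curated list, or its viral context fails. Strict context
(default) demands ≥ 1 viral-specific gene on *each* side of the candidate
on its contig; lenient mode accepts one anywhere. The strict retained set
is provably a subset of the lenient one, and the filter is idempotent on
its own retained output. The curated function list is not published as a
table; it is a user input, with a worked example list in the generator.

## What the synthetic generator does and does not emulate

`sim_communities()` draws per-vOTU base abundances from a lognormal
(σ = 1.5 — a standard rank-abundance shape; the source study does not state
a community model), multiplies a configurable fraction of vOTUs by a group
factor in the bottom-axis group (defaults: 50% of vOTUs × 10, over
20 slope + 17 bottom-axis samples, the study design it emulates), and
derives covered fractions from Poisson coverage (`1 − exp(−depth)`), so
that vOTUs below ≈ 0.105× depth exercise the zeroing rule.
`sim_genomes()` plants exact spacers, tRNAs, ≥ 70%-identity homologous
segments, terminal repeats, and per-host GC bias; predictor calls are
per-tool Bernoulli draws with set sensitivity/specificity.

None of this mimics real tool error structure, real rank-abundance
curves, strain microdiversity, or assembly artifacts. Passing the
recovery suites therefore demonstrates that the *decision layer* is
correct — that each rule accepts exactly what it defines — not that the
upstream tools' calls are reliable on real sediment data. The variant
generator introduces substitutions only (uniform over the three
alternative bases, no indels), which keeps the planted identity exactly
interpretable by a dynamic-programming alignment; the fragment-ANI
estimator is validated against that oracle to within ±0.5 identity points.

## Numerical and design choices

* Coordinates are 0-based half-open internally; the 12-column alignment
  format converts from 1-based inclusive at the I/O boundary.
* Greedy-clustering ties (equal length) break by id, making runs
  deterministic and order-independent.
* A protein's best hit breaks ties toward the lexicographically smaller
  family; exact 50/50 family ties yield `unclassified`.
* The exhaustive PERMANOVA route (`group_tests(..., exhaustive = TRUE)`)
  enumerates all size-preserving labelings and is meant for tiny designs
  where the permutation p-value can be computed exactly; its pseudo-F is
  cross-checked against vegan's.
* Degenerate inputs fail loudly: all-zero count vectors, zero-total
  samples, unknown hosts/contigs and malformed FASTA records are hard
  errors with the offending record named.

## Problem sizes used in the shipped test suites

The statistical suites run at deliberately modest sizes chosen to make the
checks sharp but cheap: type-I calibration uses 500 null communities
(80 vOTUs, 8 + 8 samples, 199 permutations) with an acceptance band of
5% ± 2%; power uses 100 seeds at the planted effect; the Markov scorer is
assessed over 100 seeds with three composition-distinct 30 kb hosts and
5 kb query contigs; ANI oracle agreement uses 50 substitution-only pairs up
to 5 kb; rule-exactness suites use ≥ 500 generated cases per rule. The
acceptance script (`scripts/acceptance.R`) re-runs the same measurements
from scratch at the same sizes plus one full 37-sample study-design
simulation.

## Known limitations

* The genus network uses connected components, not the published
  ClusterONE-style clustering; genus *counts* on real data would differ.
* CRISPR arrays are detected on assembled host sequences only, with exact
  repeat copies; read-derived array recovery and degenerate repeats are out
  of scope.
* The completeness estimator behind the quality tiers is an input, not a
  computation; only DTR detection and tier assignment are implemented.
* The host-confidence point table is a surrogate; only its ≥ 3 boundary is
  anchored to the published workflow.
* Family names follow the pre-2021 caudovirales taxonomy used by the
  reference databases; remapping to current ICTV names is a user-supplied
  table, not logic.
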