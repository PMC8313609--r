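---
title: "Profiling disease similarity from gene-disease associations"
author: "psygset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling disease similarity from gene-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psygset)
```

## The problem

Curated gene-disease association (GDA) resources such as DisGeNET attach a
set of implicated genes to each disease. Because these gene-sets are
expression-free, they allow many diseases — including psychiatric disorders
and their comorbidities — to be compared simultaneously without the
normalisation problems of cross-cohort transcriptomics. psygset implements
that comparison top-down:

1. **Similarity.** Disease gene-sets are size-filtered and compared pairwise
   with the Jaccard index \(J(A,B) = |A \cap B| / |A \cup B|\).
2. **Clustering.** A PCA of the similarity matrix followed by k-means yields
   global disease clusters; hierarchical clustering of \(1 - J\) within a
   selected cluster, with successive dendrogram cuts, yields branches and
   subgroups (the reference partition for everything downstream).
3. **Per-level profiling.** Each disease set is tested for
   overrepresentation against annotation collections at four biological
   levels — pathways, cell-type markers, drug signatures, chromosomes —
   with the exact upper-tail hypergeometric test and Benjamini–Hochberg
   (BH) FDR control.
4. **Density index.** Each annotation theme is summarised over a disease set
   by the *density index*: the fill fraction of significant cells in the
   disease × theme-annotation matrix,
   \(d = n_\mathrm{significant} / (n_\mathrm{diseases} \times
   n_\mathrm{annotations})\). Density near 1 marks processes shared across
   the diseases; near 0, processes confined to a few.
5. **Level attribution.** Diseases are re-clustered from each level's binary
   significance profiles; the Rand index (RI) between a level's partition
   and the reference partition, with a permutation p-value, ranks the levels
   by how strongly they drive inter-disease similarity.

## Statistical choices

**Overrepresentation test.** For a query of size \(n\), an annotation of
size \(K\), a background of \(N\) genes and overlap \(k\), the p-value is
the exact tail \(P(X \ge k)\), \(X \sim \mathrm{Hypergeom}(N, K, n)\)
(equivalently a one-sided Fisher test), computed by `stats::phyper` — the
standard choice for set-overlap ORA, and the one fixed here for all four
levels (a single shared test engine keeps cross-level densities
comparable). The background is the union of all genes in the *unfiltered*
GDA table: dropping diseases by size must not shrink the sampling universe.
For chromosome tests the background is additionally restricted to mapped
genes, since unmapped genes carry no information about chromosomal bias.

**FDR family.** q-values are BH-corrected within each disease across all
annotations of one collection (configurable to a global family). Pairs with
zero overlap are part of the correction family with \(p = 1\) but are not
emitted; every consumer treats absence as non-significance, so densities
and partitions are invariant to that storage choice (this is tested).

**Density variants.** The binary fill-fraction is the density index proper
and the default; a weighted variant (mean of
\(\min(1, -\log_{10} q / \mathrm{cap})\) over all cells, cap = 10) is
available behind `method = "weighted"` for users who want intensity rather
than incidence. All package invariants (weighted-mean merging of themes,
equivalence of singleton themes with single-annotation density) bind to the
binary form. Flagging thresholds (0.5 for pathway themes, 0.4 for
cell-types, 0.1 for chromosomes) are presentation defaults only; they mark
dots in reports and never enter a test.

**Rand index and its null.** RI is the fraction of item pairs on which two
partitions agree; the unadjusted form is reported as the headline statistic
(with the adjusted Rand index alongside for context) because it is the
cluster-similarity measure the density/level comparison is built around, and
p-values are attached by a size-preserving label permutation null: the item
→ label assignment of one partition is permuted uniformly, RI recomputed,
and the add-one estimator \(p = (1 + \#\{RI_\pi \ge RI_\mathrm{obs}\}) /
(1 + B)\) reported. The estimator is never 0 and is exactly valid under
exchangeability; with the default \(B = 10{,}000\), p-values near
\(10^{-4}\) are resolvable. Level partitions are cut at the reference's
cluster count so comparisons are made at matched granularity, and diseases
with no significant annotation at a level form one extra "unenriched"
cluster instead of being dropped — silently removing items would change
\(\binom{n}{2}\) and invalidate cross-level comparison. A level with *no*
significant annotation anywhere is treated by `attributeLevels()` as the
trivial all-unenriched partition (RI computable, permutation p = 1): a
signal-free level should score as uninformative, not abort the comparison.
Calling `levelPartition()` directly on such a table errors by default.

**Clustering choices.** Hierarchical clustering uses distance
\(1 - J\) with average linkage by default (the common choice for
similarity-derived distances; complete and Ward are available). How global
cluster boundaries are drawn in the PC1/PC2 plane is inherently a judgment
call when done by eye; the package fixes a reproducible surrogate — k-means
with 50 restarts under a caller-supplied seed on the top-2 PC scores —
with k a configuration key (default 3). The two-stage cut scheme (cut into
branches, select one, re-cluster, cut into subgroups) is exposed directly
in the pipeline configuration; `selectCluster`/`selectBranch` accept a
label, `"largest"`, or `"all"` for data with a single scale of structure.

## The synthetic benchmark

No public generative model of GDA data exists, so the generator makes no
distributional claims about DisGeNET; it plants the minimal structure each
downstream stage needs a ground truth for:

* **Gene sets.** 36 diseases in four subgroups of 8, 11, 11 and 6 (the
  subgroup size pattern of the psychiatric-cluster analyses this package
  is designed around), each with exactly 100 distinct genes over a
  1500-gene universe. A disease draws `coreFraction` of its genes from its
  cluster's private 200-gene pool, `sharedFraction` from a 150-gene pool
  common to all diseases, and the rest uniformly. Pools are disjoint blocks
  of the universe, so `coreFraction = 1` forces between-cluster Jaccard of
  exactly 0 — the separation-parameter limit in which clustering must
  recover the planted labels exactly, which the tests assert; raising
  `sharedFraction` degrades recovery monotonically in expectation.
* **Annotations.** Themes are built strictly inside designated pools: a
  shared-pool theme is ubiquitous (highest density across all diseases), a
  cluster-pool theme is private (densest in its own subgroup).
* **Chromosomes.** Genes are assigned uniformly at random to 22
  chromosomes; optionally one cluster's pool is biased towards one
  chromosome with probability proportional to a weight (weight 1 =
  unbiased).
* **Drugs.** Signatures sampled from a designated pool with a round-robin
  drug → mode-of-action map.

Determinism: one global integer seed drives per-entity substreams
(`seed + 1000003·i mod (2^31 - 19)`), so regenerating with more diseases
leaves earlier diseases' sets untouched and identical specs are
byte-identical on disk.

What the generator does *not* emulate — GDA evidence scores, symbol
aliasing, the severe set-size heterogeneity of real DisGeNET, overlapping
real pathway hierarchies, directional drug signatures — bounds what
passing tests show: they validate the machinery and its statistical
behaviour, not any biological claim about real disease data.

## Problem sizes and numerical notes

The test-suite and acceptance benchmarks use the 36-disease study with
replicate counts of 10–100 per property and permutation counts of 199–999;
these sizes give the planted effects comfortable margins (e.g. shared-pool
overlap expectations of 3–5× the null) while the full suite runs in a
couple of minutes on one CPU. Jaccard and RI are computed in exact integer
arithmetic and are tested for exact equality against brute-force oracles;
hypergeometric tails and BH q-values are tested to 1e-12 against
enumeration and the literal step-up formula. k-means and merge-tie
ambiguity are handled by fixed seeds and `hclust`'s deterministic tie
order; partitions are stored with canonical first-appearance labels so
label names never matter. Degenerate inputs are defined, not special-cased:
`k = 0` overlaps give p = 1 exactly, a single chromosome holding all genes
gives p = 1 for every disease, cutting a dendrogram at `k = 1` or `k = n`
gives the trivial partitions.

## Known limitations

* Gene identity is exact case-sensitive string match; symbol aliasing and
  identifier translation are curation problems upstream of this package.
* The drug level reduces connectivity-map-style comparison to set-overlap
  ORA of signature gene-sets; rank-based connectivity scoring is out of
  scope, as are directional (up/down) signatures.
* The density index treats significance as binary at a single q threshold;
  conclusions can shift with that threshold, which is why it is recorded in
  every output.
* Size-filter bounds (default 10–1000) and all cut/threshold choices are
  configuration, not estimates; the pipeline manifest records every
  parameter and seed so a run is reproducible from its run directory alone.
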