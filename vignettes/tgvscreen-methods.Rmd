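---
title: "Methods: fingerprint clustering, network pharmacology, and energy bookkeeping in tgvscreen"
author: "tgvscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint clustering, network pharmacology, and energy bookkeeping in tgvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgvscreen)
```

## Overview

`tgvscreen` is a virtual-screening toolkit for herbal compound libraries,
built around a single idea: reduce a library of hundreds of structurally
related natural products (for example the triterpenoids, sesquiterpenoids
and flavonoids of thunder god vine, *Tripterygium wilfordii*) to a small
panel of representative molecules, then push those representatives through
a network-pharmacology and binding-energy triage. The chain is

1. **Fingerprints.** Each molecule becomes a binary substructure vector.
2. **3-D embedding.** t-SNE projects the fingerprints into three
   dimensions.
3. **Hierarchical clustering.** The embedded points are agglomerated and
   the tree is cut into *k* chemical families.
4. **Tanimoto representative selection.** Each family is represented by
   its Tanimoto medoid — the member with the highest mean similarity to
   the rest of its family.
5. **Network pharmacology.** Representatives' predicted protein targets
   are intersected with merged disease-gene sources; molecules are ranked
   by overlap, hub genes by degree in a PPI network, and gene sets by a
   hypergeometric enrichment statistic.
6. **Energetics.** Docking score tables are screened for the lowest-energy
   molecule-target combination; MM/PBSA per-snapshot components are
   aggregated; hydrogen-bond occupancies are tallied from trajectory
   frames.

Everything downstream of public databases and simulation engines is
implemented here; querying those databases, running docking or molecular
dynamics, and trajectory geometry (RMSD, radius of gyration, SASA, RMSF)
are out of scope. The package therefore operates on their *outputs*:
SMILES libraries, gene tables, edge lists, GMT annotation files, and
score/snapshot/frame tables.

## Fingerprints and similarity

Two schemes are supported because the field uses both and the published
descriptions of this workflow are ambiguous between them:

* `maccs` — the 166-key MACCS substructure fingerprint, computed through
  OpenBabel. This is the default.
* `hashed` — a 2048-bit hashed topological fingerprint: every simple
  linear atom/bond path of up to seven bonds is enumerated on the
  canonical structure, direction-normalised, and hashed (FNV-1a) onto one
  of 2048 bit positions. This is the Daylight-style construction and gives
  a fixed-width vector independent of any reference library.

Molecules are canonicalized before fingerprinting, so `CCO` and `OCC`
yield identical bits; the input string is preserved for reporting.
All-zero fingerprints are rejected at construction rather than defining a
0/0 Tanimoto convention — real molecules always set keys, and an all-zero
vector invariably signals a degenerate input.

Similarity is the Tanimoto coefficient
$T(a,b) = |a \cap b| \, / \, |a \cup b|$ on set bits; `similarity_matrix()`
computes it for a whole library with exact unit diagonal and enforced
symmetry.

## The 3-D embedding

`tsne_embed()` is a from-scratch t-SNE: per-point Gaussian bandwidths are
calibrated by bisection (50 iterations, entropy tolerance `1e-5`) so each
conditional distribution's entropy equals `log(perplexity)`; conditionals
are symmetrized into joint affinities; the low-dimensional kernel is
Student-t with one degree of freedom; and the KL divergence is minimized
by momentum gradient descent (momentum 0.5 then 0.8) with adaptive gains
and an early-exaggeration phase.

Defaults — perplexity 30, 1000 iterations, learning rate 200, early
exaggeration 12 for the first 250 iterations — are the standard published
settings; the perplexity is capped at $(n-1)/3$ at run time so small
libraries remain feasible. A seed is mandatory and the embedding is
bit-identical for a fixed (input, config) pair; the caller's RNG state is
left untouched.

The distance fed to t-SNE is the Jaccard distance $1 - T(a,b)$ on
fingerprints by default, keeping the whole chain on the Tanimoto scale;
Euclidean distance on raw bits is selectable. Duplicate molecules produce
zero off-diagonal distances, which receive an additive jitter of `1e-10`
before bandwidth calibration so the bisection cannot divide by zero.

## Agglomeration and the cut

`agglomerate()` merges the closest pair of clusters at every step, with
Lance–Williams updates for single, complete, average and Ward linkage
(Ward updates act on squared Euclidean distances; recorded heights are on
the distance scale, so two singletons merge at their Euclidean distance).
Ties in the nearest-pair search are broken by the smallest (left, right)
cluster-index pair, making the merge sequence fully deterministic. The
default is Ward on the 3-D coordinates — the common choice for compact
chemical families.

The test suite holds this implementation against a naive $O(n^3)$
re-agglomeration oracle that recomputes every inter-cluster distance from
the raw points at every step (and, for Ward, uses the closed-form
centroid distance $\sqrt{2 n_A n_B/(n_A+n_B)}\,\lVert \bar x_A - \bar x_B
\rVert$), and against `stats::hclust` merge heights.

`cut_to_k()` undoes the last $k-1$ merges, guaranteeing exactly $k$
non-empty clusters. $k$ is a user parameter with default 6: the workflow
this package supports reports six chemical families for its flagship
library, but publishes no cut criterion, so the count is exposed rather
than inferred. Whether six arose from a dendrogram cut or by inspection is
unknowable from the published description; a cut at $k$ is the
reproducible reading.

## Representative selection

A cluster's representative is its Tanimoto medoid: the member maximizing
the arithmetic mean similarity to the *other* members (self excluded;
including the self term would shift every mean by the same $1/m$ mixture
and cannot change the argmax, but it would inflate reported values, so
the excluded form is reported). Singleton clusters get mean similarity 1
by convention. Ties — which occur in practice only for identical
structures — resolve to the lexicographically smallest molecule id.
Similarity is computed within the cluster only, not against the whole
library.

## Network pharmacology

* **Source merging.** `merge_disease_genes()` unions any number of
  disease-gene sources after a relevance filter: scored records must
  exceed the threshold (default 5) *strictly* — the literal reading of a
  "score of over 5" rule — with `strict = FALSE` available for the
  inclusive reading. Unscored sources pass through. Symbols are
  upper-cased and trimmed; alias resolution would need live databases and
  is deliberately absent.
* **Ranking molecules.** `rank_molecules()` counts each molecule's
  predicted targets inside the disease set and sorts descending, ties by
  id.
* **Hub genes.** `top_hubs()` ranks nodes by plain degree — the default
  hub notion of the standard network-analysis tooling — ties by symbol.
  Other centralities are out of scope.
* **Enrichment.** `hypergeom_enrich()` computes the upper-tail
  hypergeometric probability $P(X \ge k)$ for $k$ annotated genes among
  $n$ query genes drawn from a universe of $N$ with $K$ annotated, then
  applies Benjamini–Hochberg across terms. The universe defaults to the
  union of the GMT annotation sets — an explicit, reproducible choice —
  and a query gene outside the universe is an error naming the offender.
  Annotation databases themselves are supplied by the user as GMT.
* **Hub expansion.** `merge_neighbor_lists()` is the deduplicated union
  of hub genes with per-hub functional-neighbour lists — the arithmetic
  behind growing a hub-centred gene database from association queries.

## Energetics bookkeeping

`best_combination()` scans a docking table for the minimum energy row
(optionally per target), ties by molecule then target id. On the bundled
table of six triterpenoid ligands against PPARG and PTGS2 it returns
Hederagenin at −8.8 kcal/mol for PTGS2 and Triptonide at −6.5 kcal/mol
for PPARG.

`aggregate_snapshots()` derives per-snapshot
$\Delta G_\mathrm{gas} = \Delta E_\mathrm{vdw} + \Delta E_\mathrm{ele}$
and $\Delta G_\mathrm{total} = \Delta G_\mathrm{gas} + \Delta
G_\mathrm{solv}$, then reports the mean and *sample* (n−1) standard
deviation per column — the convention of MM/PBSA reporting tools. The
component identities hold exactly on the means by construction.

Printed-table comparisons use `round()` (round-half-even) at two
decimals with a 0.01 kcal/mol tolerance: published component tables are
routinely rounded column-by-column, so a sum of rounded components can
differ from the printed rounded sum by one unit in the last place. The
bundled tables exhibit exactly this: six of twelve rows are off by ±0.01
from their own printed components, and the tolerance absorbs it without
masking real errors.

`hbond_stats()` treats a donor–acceptor pair as present in a frame if it
forms at least one bond there (repeats count once for occupancy, but each
bond record counts toward the bonds-per-frame mean). Occupancy is the
percentage of frames containing the pair. Frames with no bonds at all
still belong in the denominator; since a bond-record CSV cannot encode
them, rows with empty donor and acceptor act as frame markers, and
`n_frames` can be passed explicitly.

Transcribed tables often carry the Unicode minus (U+2212); all CSV
readers normalise it to ASCII on input.

## Synthetic generators and what they do (not) show

Every pipeline input has a seeded generator with exact ground truth, so
all stages are testable without downloads:

* `gen_fingerprint_library()` plants $k$ chemical families: bit positions
  are split into $k$ disjoint blocks, each family's prototype sets 80% of
  its block, and each member *drops* each prototype bit independently with
  probability $p$ (`flip_prob`). The noise is deliberately one-sided
  dropout rather than a symmetric per-position XOR: with near-disjoint
  prototypes, symmetric flipping at any realistic bit width caps the
  expected within-family Tanimoto near 0.6 even at $p = 0.05$, which is
  not what curated congeneric series look like. Under dropout the expected
  within-family Tanimoto is $(1-p)^2/(1-p^2)$ — about 0.90 at $p = 0.05$,
  exactly 1 at $p = 0$ — while between-family similarity stays at 0. This
  emulates substructure variation within a scaffold family.
* `gen_gene_fixtures()` builds a target map whose per-molecule overlap
  with the disease set matches a requested spec exactly, plus non-disease
  decoys.
* `gen_network()` realizes a degree sequence (Havel–Hakimi, deterministic)
  with strictly decreasing planted hub degrees above a low-degree
  background, so the degree ranking is unambiguous by construction.
* `gen_mmpbsa_snapshots()` draws Gaussian component samples; zero standard
  deviations reproduce the means exactly.
* `gen_hbond_frames()` is count-exact: each pair appears in exactly
  `occupancy/100 * n_frames` frames (which must be whole), so occupancy
  targets are deterministic rather than Bernoulli — sharper tests at the
  cost of not modelling occupancy sampling noise.

What passing these tests shows: the algorithmic chain recovers planted
structure whose separation is, by construction, strong (disjoint prototype
blocks, between-family Tanimoto ≈ 0). What it does not show: performance
on real libraries, where families overlap in substructure space, sizes
are imbalanced, and the "true" family count is undefined. The generators
also produce fingerprints directly; chemically valid synthetic SMILES at
scale are out of scope (a small hand-written SMILES file ships for parser
tests).

## Numerical choices, in one place

* Bandwidth bisection: 50 iterations, entropy tolerance `1e-5`; affinity
  floor at machine epsilon.
* Zero-distance jitter: `1e-10`, additive, before calibration.
* Nearest-pair ties: smallest (left, right) index pair.
* Representative ties: lexicographically smallest id.
* Ranking ties (molecules, hubs): id/symbol ascending.
* Standard deviation: sample (n−1); a single snapshot reports 0, not NA.
* Table rounding: round-half-even at 2 dp, 0.01 kcal/mol tolerance.
* Degenerate inputs: all-zero fingerprints, empty clusters, empty
  networks, empty merged gene sets, zero frames and non-finite energies
  are errors, not silent conventions.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full chain on a planted
library of 6 families × 20 members at 166 bits with 5% dropout (n = 120
molecules), the oracle-equivalence loops on 100 random instances of up to
40 points across all four linkages, enrichment enumeration on universes up
to N = 12, and occupancy fixtures of 1000 frames — sizes at which the
brute-force oracles are exact and the whole suite completes in well under
a minute on a single core.

## Limitations

* MACCS keys come from OpenBabel's pattern set; other toolkits' MACCS
  implementations differ in a handful of keys, so absolute bit patterns
  (not the algorithm's behaviour) are toolkit-specific.
* t-SNE is a stochastic embedding: different seeds give different (all
  valid) 3-D layouts, and cluster recovery is guaranteed only in the
  strong-separation regime the generator plants.
* Degree is the only hub statistic; betweenness or closeness rankings can
  differ on real PPI networks.
* No entropy term, strain correction or per-residue decomposition in the
  MM/PBSA bookkeeping — it aggregates what the upstream tool emitted,
  nothing more.
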