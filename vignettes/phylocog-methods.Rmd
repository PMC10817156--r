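---
title: "Methods: phylogenetic profiling of orthologous-group association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic profiling of orthologous-group association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocog)
```

## The model

Orthologous groups (COGs for mostly prokaryotic families, KOGs for
eukaryotic ones; we write "COG" for both) carry functional-association
confidence scores on pairs of groups, integers on a 0--1000 scale, with
larger meaning stronger combined evidence that the two groups work
together. Around a user-chosen *seed* group, the package builds a picture
of how the seed's functional neighborhood is conserved across the tree of
life:

1. **Neighborhood selection.** Every group whose direct association score
   with the seed reaches a cutoff `c` joins the column universe. The
   boundary is inclusive (`score >= c`): the preset cutoffs (900, 850, 800,
   750, 700) are round numbers users expect to be attainable. Only
   seed-incident edges matter; neighbor--neighbor edges are retained in the
   association table but unused, because every heatmap cell is later
   weighted by the seed-to-column score specifically.
2. **Profiling.** For each clade (phylum or class) and each column group,
   the presence frequency is the fraction of the clade's organisms
   possessing at least one protein of the group. Paralogs count once; the
   denominator is the full clade roster, because absence of a genome's
   worth of evidence is itself informative.
3. **Binarization.** A cell becomes 1 when its frequency is at least the
   threshold (default 0.5), 0 otherwise. The boundary is inclusive: a clade
   where exactly half the organisms possess the group is scored present,
   matching the rule "less than half gives 0, 1 otherwise".
4. **Weighting.** Present cells take the value of their column's
   seed-association score, so the heatmap encodes both conservation and
   association strength. The seed's own column has no stored self-score;
   it is imputed at the scale maximum 1000, which keeps the column on the
   same color scale (the seed is trivially maximally associated with
   itself).
5. **Biclustering.** Rows and columns are clustered independently
   (hierarchical agglomeration; euclidean distance and complete linkage by
   default) and each axis is cut into a user-chosen number of clusters
   (presets: 2--6 column clusters, 3--5 row clusters). Each (column
   cluster, row cluster) intersection is a rectangular *module*, addressed
   `(c, r)` with `c` the COG cluster and `r` the phylogenetic cluster.
6. **Enrichment.** With `N` the total cell count, `H` the number of
   present (nonzero) cells, `n` a module's cell count and `h` its present
   cells, each module gets exact hypergeometric tail probabilities
   (`stats::phyper`/`dhyper`). The upper tail is inclusive,
   `P[X >= h]` — the standard enrichment convention, stated explicitly
   because the exclusive default of `phyper` is a known trap. Both tails
   are always reported and the consumer picks; no tail choice is silently
   made. `e_over`/`e_under` are transparent Bonferroni-style expected
   counts (tail probability times module count, capped at the module
   count); they are this package's explicit convention, reported alongside
   the raw probabilities rather than instead of them.

## Clade assignment

Lineage dumps carry names without rank labels, so ranks are read
positionally from lineages rooted at `cellular organisms`: element 3 is
the phylum and element 4 the class (root, superkingdom, phylum, class,
...). The convention is overridable per run (`rank_index_map`) and per
organism (a two-column override table). Organisms whose lineage is too
short, or rooted elsewhere (viruses, for instance), are excluded and
counted in the log rather than silently misassigned — a misassigned
organism would corrupt the presence denominator of a clade it does not
belong to.

## Clustering: numerical choices

Agglomeration is implemented through the Lance--Williams recurrence so
that every numerical convention is pinned down:

* **Linkages.** complete (default), single, average, median, ward_d,
  ward_d2, centroid. ward_d applies the Ward coefficients to the distances
  as given; ward_d2 applies them to squared distances internally and
  reports heights back on the input scale. centroid and median likewise
  operate on the distances as given, matching the common implementation
  behavior; for exact geometric centroids they would want squared
  euclidean input.
* **Tie-break.** When two candidate merges share the minimal distance, the
  lexicographically smallest pair (smaller position, then larger position)
  wins, where a merged cluster inherits the smaller parent position. Ties
  essentially never arise on real weighted profiles, but the rule makes
  results bit-reproducible across platforms.
* **Leaf order.** At each merge the earlier-created subtree is placed
  first (leaves before merged clusters, earlier merges before later ones).
  No optimal-leaf-ordering pass is applied: reproducibility is preferred
  over aesthetics.
* **Cutting.** `cut_dendrogram(d, k)` undoes the last `k - 1` merges
  (equivalently, removes the `k - 1` highest merges under monotone
  linkages, and remains well defined under the inversions that centroid
  and median can produce). Clusters are numbered 1..k by first appearance
  along the leaf order, so module addresses read off the rendered heatmap
  left-to-right and top-to-bottom.
* **Minkowski exponent.** `minkowski_p` defaults to 3: p = 1, 2 and
  infinity are already available as the named manhattan, euclidean and
  maximum metrics.

In tests, the implementation is checked against two independent routes: a
naive cubic Lance--Williams re-implementation (merge sequence and heights,
tolerance 1e-9) and `stats::hclust` (heights and cut partitions) on
tie-free random matrices, for all seven linkages and four metrics.

## Seed resolution from sequence

When only a protein sequence is known, the seed group is inferred by
alignment against a non-redundant per-group reference. The reference is
built by greedy incremental clustering in the style of cd-hit: sequences
sorted by length descending (ties by id), each joining the first existing
representative with identity at or above 0.8, else founding a new one.
Identity is matching positions divided by the length of the shorter
sequence — cd-hit's denominator — under global alignment; the same
denominator is used for query resolution under local alignment, so a short
perfect fragment cannot masquerade as a near-full-length match. Alignment
parameters are BLAST-like defaults (BLOSUM62, gap open 11, extend 1); the
underlying alignments are computed by Biostrings. A shared 5-mer prescreen
limits the alignment set; tests verify it is a pure speedup by comparing
against exhaustive all-vs-all alignment. Queries are accepted at identity
0.5 by default and flagged low-confidence below the 0.8 build threshold:
the build threshold is well defined, but an acceptance threshold for
queries is genuinely open, so it is exposed and conservative defaults are
flagged rather than hidden.

## What the synthetic data emulates

`fixture_spec()`/`generate_fixture()` produce the four flat files with a
planted block structure: clades and network groups are split contiguously
into blocks, an organism of clade block `r` possesses a group of block `b`
with probability `block_design[r, b]` (optionally XOR a Bernoulli noise
flip), each group block draws seed-association scores from its own integer
interval, and decoy groups get scores strictly below the design cutoff.
The reference conditions used by the acceptance script and the heavier
tests are 12 clades of 6 organisms and 20 network groups in a 3 x 3
diagonal design with disjoint score intervals ([700, 790], [810, 890],
[910, 990]), 3 decoys and no noise; smaller variants (9 clades of 4, 12
groups) keep the test suite fast. One RNG stream per file type, each
derived from `rng_seed`, makes bundles byte-identical across runs.

The generator emulates the *statistical* structure the method assumes —
blocks of co-present groups with distinct association strengths — not real
evolutionary processes: there is no birth--death gene gain/loss model, no
phylogenetic correlation between clades, and no emulation of how evidence
channels combine into association scores. Passing the planted-recovery
tests therefore shows the machinery recovers structure it is pointed at,
not that real datasets contain such clean blocks.

A noiseless spec must use presence probabilities only from {0, 1}; with
probabilities in the open interval, a positive noise rate declares the
stochasticity explicitly. Under the noiseless diagonal design the realized
binary matrix is exactly block-diagonal, recovery at the true cluster
numbers is exact (adjusted Rand index 1 on both axes), and raising the
noise rate degrades mean recovery — both properties are asserted over 20
seeds in the acceptance suite.

## Degenerate inputs and edge cases

* An empty neighborhood is a valid network (the seed column alone);
  biclustering requires at least 2 rows and 2 columns and says so.
* Clades with empty rosters are excluded with a warning; all-zero clade
  rows are kept by default (all-light rows are themselves informative) and
  can be dropped with `drop_empty`.
* Readers validate everything before returning — score ranges, group-id
  patterns, duplicate records, conflicting symmetric scores — and report
  file line numbers; no partially validated data escapes.
* The association table stores unordered pairs: lookups are symmetric and
  self-pairs are rejected at construction.

## Outputs

`run_pipeline()` writes the weighted matrix, the two cluster membership
tables, the per-module enrichment table, the per-cell annotation table
(clade, group id with description, possessing-organism count, score — the
four hover fields), an SVG heatmap, and a run log that records every
convention in force (inclusive boundaries, imputed seed weight, tie rule,
exclusion counts). The SVG is emitted directly — one `rect` element per
cell, boundary lines at cluster breaks, a 0--1000 legend — so that
structural properties are testable on the text. The color scale runs light
yellow through cherry red to black (weak to strong association); anchor
values are stylistic, the mapping is strictly monotone in luminance. All
tabular outputs are TSV and byte-stable under reruns.

## Known limitations

* Clade extraction is positional; lineages not rooted at "cellular
  organisms" require the override table.
* The greedy clusterer reproduces cd-hit's *convention*, not its exact
  cluster outputs (cd-hit's short-word statistics and heuristics are out
  of scope).
* Module addresses depend on the leaf-order convention; other tools using
  different dendrogram orderings will number the same partitions
  differently.
* The hypergeometric model treats cells as exchangeable draws; rows of
  related clades are not independent, so module probabilities are
  descriptive scores rather than calibrated significance levels for
  correlated data.
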