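---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treekit)
```

This vignette documents the models and procedures `treekit` implements,
the conventions it fixes where the underlying methods leave choices open,
and what its synthetic-data generators do and do not establish.

## The tree model

Trees are rooted, with ordered children, per-edge branch lengths
(default 1 when a newick string carries no `:x`), optional per-edge
support in $[0,1]$, and an open annotation map per node. Two conventions
matter downstream:

* **Absent support is not zero.** A branch with no support label has
  `NA` support, and `collapse_low_support()` never contracts it: missing
  data is not evidence of weakness. Only branches with stated support
  below the threshold are collapsed (children are lifted into a
  polytomy, with the contracted edge's length added to theirs so
  root-to-leaf path lengths are preserved).
* **Internal-label ambiguity.** Newick writes support and internal names
  into the same slot. The default dialect reads a bare numeric internal
  label in $[0,1]$ as support and anything else as a name; the
  `named-internal` and `support-as-label` dialects override this when
  the producer's convention is known. Nothing in the format itself
  resolves the ambiguity, so the flag is the only honest interface.

Child order is preserved exactly as parsed and serialization is
deterministic, so parse–write round-trips are identities and CLI output
is byte-stable.

## Robinson–Foulds distance and congruence

All split-based comparison uses *unrooted* semantics: one bipartition
per internal edge, both sides restricted to the comparison universe and
required to keep at least two labels; a degree-2 root's two edges induce
the same split once, so differently rooted copies of one tree are at
distance 0. Trees of unequal size are compared on their shared leaf set
(the `strict` policy instead errors, for pipelines that must not prune
silently); fewer than three shared leaves leaves nothing to compare and
is an error.

Two degenerate-case conventions are fixed here and used consistently:

* When both trees contribute zero nontrivial splits on the shared
  universe (e.g. exactly three shared leaves, or two stars), `max_rf`
  is 0 and `norm_rf` is reported as 0 — no discriminating splits, no
  disagreement.
* Branch congruence for a tree with zero nontrivial splits is `NA`,
  never 100: a star tree cannot *agree* with anything, and claiming
  full congruence from vacuity would bias batch summaries upward.

## Species-overlap duplications and TreeKO decomposition

Gene-tree leaves map to species by the common `species_gene` label
convention (prefix before the first `_`; an explicit table overrides; a
label without the delimiter maps to itself, so species trees pass
through). An internal node is a duplication when its children's species
sets overlap: score $= |S_a \cap S_b| / |S_a \cup S_b| >$ threshold.
The default threshold 0 calls any overlap a duplication; raising it
tolerates sparse overlaps (e.g. suspected misplaced paralogs). A
polytomy is a duplication if *any* pair of its children overlaps beyond
the threshold — the consistent generalization of the binary rule.

The decomposition is the standard recursion: a leaf yields itself; a
duplication node yields the union of its children's pruned-tree sets
(folding the node's branch length into each subtree so path lengths are
conserved); a speciation node yields every combination of one pruned
tree per child. Subtree counts therefore multiply at speciation nodes
and add at duplication nodes, which makes the output size geometric in
the number of nested duplications: enumeration is guarded by
`max_subtrees` (default 1000) with a hard error rather than silent
truncation, because a truncated sample would bias every downstream
distance.

### Speciation distance

The distance between two trees is the weighted mean of normalized RF
over all pruned-tree pairs sharing at least 3 species. Two choices here
are ours, exposed as switches rather than buried:

* **Pair weighting.** Weights are proportional to the pair's
  shared-species count (`weighting = "shared"`), on the grounds that a
  pair overlapping in 8 species carries more topological information
  than one overlapping in 3; `"uniform"` is available for sensitivity
  checks.
* **Minimum overlap 3.** A pair sharing fewer than 3 species has no
  nontrivial splits at all, so it is excluded from both the numerator
  and the normalizer (not scored 0, which would fake agreement). When
  no pair qualifies the distance is `NA` with an explicit reason.

Note that with unrooted split semantics any pair sharing exactly 3
species contributes normalized RF 0; pairs only begin to discriminate at
4 shared species. Support filtering, when requested, is applied to both
trees symmetrically.

### Gene-tree support mapping

For each nontrivial split of a single-copy reference tree, every pruned
tree is tested after restricting the split to the pruned tree's species:
it is *informative* when both restricted sides keep ≥ 2 species, and
*supporting* when its own (restricted) split set contains the restricted
split. Pruned trees inherit weight $1/m$ from a gene tree that produced
$m$ of them, so one heavily duplicated family cannot dominate a branch's
support fraction.

## Taxonomy store

The taxdump dialect (`\t|\t` separators, `\t|` terminators) is parsed
bit-compatibly with real NCBI dumps while all shipped fixtures are
synthetic, generated by `synthetic_taxdump()`. Build-time validation is
strict (orphan parents and nameless taxids are fatal); query-time
failures are soft in batch translators (missing lists) and hard in
single-subject queries (lineage), because batch pipelines must survive
partial data but a lineage of an unknown id has no meaningful value.
Merged-id chains are collapsed at build so every lookup follows at most
one redirect hop. The persistent store is a single deterministic
plain-text file — no embedded SQL engine is required at this scale, and
byte-identical rebuilds make caching trivially verifiable. Name matching
is case-insensitive with whitespace collapsed; fuzzy matching is
deliberately out of scope.

In `get_topology()`, an input taxid that is an ancestor of another input
becomes an annotated *internal* node of the result rather than a
duplicated leaf — the subtree is a pruned restriction of the taxonomy,
not a flat list.

## Likelihood ratio tests and classification

`lrt()` uses the plain $\chi^2_{df}$ reference with
$df = \Delta\text{parameters}$, which is the conservative default; the
50:50 boundary mixture sometimes recommended for branch-site tests is
available via `mixture = TRUE` but not default, since the plain test is
never anticonservative here. Negative $D$ from optimizer noise is
clamped to 0 with a warning rather than an error — real CodeML runs
produce tiny negative improvements routinely. Nestedness is asserted
against a registered pair table (M1/M2, M7/M8, M0/M3, bsA1/bsA,
M0/b\_free, M0/fb); unregistered pairs require an explicit `df`, making
accidental non-nested comparisons loud. Multiple pairs are
Bonferroni-adjusted alongside the raw p-values (simplest defensible
correction; the best-fit flag uses the raw value at $\alpha = 0.05$).

Branch classes use the thresholds 0.2 and 1 with the interval
$[0.2, 1]$ read inclusively on both ends ("between 0.2 and 1"), so
$\omega = 0.2$ and $\omega = 1$ are both `relaxed`; $\omega = \infty$
(no synonymous substitutions observed) is `saturated`. Site classes use
strict inequalities at 0.01 and 0.05. Running CodeML/SLR and parsing
their native outputs is out of scope; the versioned three-section TSV
(`#model_fit` header, `#branches`, `#sites`) is the interchange point,
with `inf` as the explicit saturated-omega token.

## Supermatrix concatenation

Columns are appended in input order; the union policy pads a species
missing from a partition with `?`, not `-`, because downstream inference
tools distinguish "no data" from "alignment gap". Species are joined by
exact label only — silent fuzzy joins are the worst failure mode of
supermatrices. Partition tables are emitted in RAxML syntax (`WAG`/`DNA`
placeholder models) and plain TSV.

## Synthetic data: what it emulates and what it does not

`random_tree()` draws binary topologies by uniform random joins with
exponential branch lengths (mean 0.1 substitutions/site — a typical
scale for single-gene trees), fully reproducible from a seed and
isolated from the global RNG. The test suite's gene-tree generator
samples species assignments with replacement to create realistic
duplication structure. These fixtures exercise the *combinatorics* of
the methods (split enumeration, decomposition counting laws, metric
identities) against brute-force oracles; they do not emulate
substitution-model heterogeneity, alignment error, or biased gene loss.
A green suite therefore establishes algorithmic correctness, not
robustness to real-data pathologies.

Numerical conventions: branch lengths are serialized with up to 17
significant digits so round-trips are exact; leaf path-length
preservation under re-rooting is asserted to $10^{-9}$; all tie-breaks
(child order, descendant ordering in taxonomies) are deterministic, so
identical inputs give byte-identical outputs everywhere, including the
CLI.

## Known limitations

* Pruned trees produced under a *positive* overlap threshold can retain
  duplicate species; split-based comparison rejects such trees loudly
  rather than guessing a resolution.
* NEXUS/phyloXML input, branch-length-aware distances (branch score,
  quartet distances) and the strict TreeKO variant are not implemented.
* Taxonomy name search is exact (normalized); there is no fuzzy or
  partial matching.
* The CLI's `ncbiquery` resolves an ambiguous name to its first
  (lowest-taxid) hit; the R API returns all hits.
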