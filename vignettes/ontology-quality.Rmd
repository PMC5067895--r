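---
title: "Measuring structural quality and evolution of OWL ontologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring structural quality and evolution of OWL ontologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oquare)
```

## What the package measures

`oquare` evaluates the *engineering* quality of an OWL ontology — structural
properties a reviewer can measure without domain knowledge — and tracks how
that quality evolves across releases. The pipeline has four stages:

1. **Structural graph.** An OWL file (RDF/XML or Turtle) is reduced to a
   uniform view: the named-class is-a DAG under the implicit root
   `owl:Thing`, property declarations, property *usages*, annotation
   assertions, individuals and deprecation flags. A usage is one occurrence
   of a property inside a class-expression axiom (an existential, universal,
   value or cardinality restriction under `rdfs:subClassOf` or
   `owl:equivalentClass`) or one property assertion on an individual.
   Declarations and domain/range axioms are deliberately not usages: usage is
   meant to measure how often a property actually links entities, and that
   reading also reproduces the usage-dominated behaviour of the
   relationship-richness metrics on real corpora. Anonymous class
   expressions never enter the class set, but their restrictions count.

2. **Fourteen metrics.** Raw values computed from the graph (see
   `?compute_metrics` for the exact formulas). Conventions that matter:
   path lengths are counted in edges with the implicit root as an endpoint,
   so a single-class ontology has depth 1; "subclasses of Thing" in the
   coupling denominators means *direct* children of the root; cohesion
   (LCOMOnto) averages over *every distinct* leaf-to-root path, so a
   multi-parent class contributes one path per parent choice; and
   tangledness (TMOnto) is the *fraction* of classes with more than one
   direct parent.

3. **Scaling.** Raw values become quality scores 1–5 under a fixed static
   scale and/or a corpus-fitted dynamic scale.

4. **Evolution statistics.** Score differences between consecutive versions
   are summarised per pair (frequency distribution of change levels, mean
   and magnitude of change, accumulative profile), pairs are ranked by a
   Wilcoxon signed-rank test on the raw differences, and quality change is
   related to editing activity (classes added/deleted/changed) by PCA and
   Pearson correlations.

## Design choices in the metric definitions

Two of the fourteen formulas are stated ambiguously in the framework's
published descriptions, and the package resolves them as follows.

**Tangledness.** The framework's own worked example quotes a tangledness
raw value of 1.28 ("mean number of classes with more than 1 direct
ancestor"), yet all observed corpus values and the accompanying narrative
("10 % of the classes had more than 1 direct parent") are fractions in
[0, 1]. We define TMOnto as the fraction of multi-parent classes. The static
scale's lowest printed bin for TMOnto starts at 1, so fractional values
below 1 clamp to the best score — a documented consequence of this
resolution. The 1.28 example still scores 5, as published, because it falls
in the (1, 2] bin.

**Coupling vs direct children.** CBOnto ("number of superclasses …") counts
every direct-superclass link including the implicit link to the root carried
by parentless classes; NOCOnto ("mean number of direct subclasses …")
counts only edges between named classes. This distinction is what makes the
two metrics differ on real corpora, where published values show CBOnto
consistently above NOCOnto.

Metrics with a zero denominator (e.g. CBOnto when every class is a direct
root child) are reported as `NA`, an explicit undefined marker — never
infinity. Aggregation drops undefined components with a warning and
renormalises the weights. Cyclic is-a graphs are an error at load time, not
silently broken: the path metrics are simply undefined on cycles. LCOMOnto
enumerates paths with a memoised traversal that is linear in the number of
edges; the number of *distinct* paths can still be exponential in
pathological DAGs, so enumeration is capped (default 10^6 paths) with an
error beyond the cap.

## The two scales

The **static scale** is the fixed threshold table: nine object-oriented
metrics are lower-is-better with absolute bins (e.g. depth `[1, 2] → 5`,
`(2, 4] → 4`, …, `> 8 → 1`), and the five ratio metrics are
higher-is-better in percentage bins (`[0, 20] % → 1` up to `> 80 % → 5`).
Bins are half-open exactly as printed, so cohesion 2.0 scores 5 while
2.0001 scores 4. Out-of-table values clamp to the nearest bin: ratios above
100 % score 5.

The **dynamic scale** adapts to a versioned corpus: for each metric, the raw
values observed across all versions are clustered into at most five groups,
and groups are mapped to scores so the best observed value scores 5. Where
the published method ran a generic k-means (whose result depends on
initialisation), this package computes the *exact* optimum: in one
dimension the variance-minimising partition is contiguous on the sorted
values, so dynamic programming over the sorted distinct values (weighted by
multiplicity) finds the global minimum of the within-cluster sum of squares
deterministically, with no seed. The test suite verifies this against
exhaustive enumeration of all contiguous partitions. When a metric has
fewer than five distinct values, the *low* score categories are left empty —
the best value must still score 5 — which is exactly the published behaviour
for the depth metric of a real 14-version corpus (four distinct values,
scores 5..2 occupied, score 1 empty). Out-of-hull values clamp to the
nearest fitted interval, ties resolving to the better score.

The two scales answer different questions: the static one positions a
version against fixed engineering practice; the dynamic one resolves
version-to-version movement that the static bins are too coarse to see.

## Evolution statistics

For score vectors `s_{i-1}` and `s_i` over the same `r` metrics and the same
scale, the change in scale is `l_i = s_i - s_{i-1}` with levels in −4..4,
and `F_i` is its frequency distribution (counts always sum to `r`). Derived
statistics: forward (backward) mean change — the weighted mean over the
positive (negative) levels, *undefined* when no component moved in that
direction; forward/backward size — the corresponding numerators in absolute
value, defined even when the means are not; mean change `Σ l·f_l / r`,
identically `(forward size − backward size)/r`; and magnitude — the
percentage of metrics whose score changed. Undefined values are `NA`
throughout and print as `-` in the exported tables; they are never coerced
to zero except in the accumulative profile, where an undefined mean change
contributes zero and is flagged. Statistics for a version are always
computed against the previous *processed* version, so corpora with
unparseable releases skip them rather than breaking the chain.

Two worked rows of the framework's own running example are internally
inconsistent in the published text (the printed change row for the fifth
version does not equal the difference of its score rows, and the quoted
magnitude "of version 2" matches version 3's distribution). The definitions
govern; those two rows are not used as test anchors.

Consecutive version pairs are ranked by the sample median of the absolute
raw metric differences (the "critical value") together with a one-sided
Wilcoxon signed-rank p-value for the alternative that the median difference
exceeds zero. The null distribution is computed exactly (zeros dropped,
mid-ranks for ties, convolution over the doubled ranks) for n ≤ 20; since
the absolute differences are all positive, the statistic is maximal and the
exact p-value for 14 untied metrics is 2^−14 ≈ 6.1e−5. Published analyses
that used the normal approximation report slightly larger p-values for tied
configurations; the exact tail is used here deliberately.

The PCA relates the dynamic-scale change statistics (backward size, forward
size, mean change) to the three activity counts per pair (classes added,
deleted, changed — the Bubastis variables). Variables are standardised, so
this is PCA on the correlation matrix; the published account does not state
the matrix choice, and correlation is the defensible default for variables
with heterogeneous units. Loadings are reported as variable–component
correlations and are sign-indeterminate; tests compare absolute values.
Constant variables (common in short corpora) are excluded with a warning.
A class counts as "changed" when its local fingerprint differs: direct
parents, restrictions, annotations, deprecation flag, individuals and their
assertions. The published diff tooling does not say whether annotation-only
edits count as changes; we fingerprint both logical axioms and annotations,
since annotation edits are real editorial activity.

## Normalisation

Deprecated classes accumulate in biomedical ontologies (kept for backward
compatibility) and distort structural metrics. `normalise_graph()` removes
them together with every axiom that mentions them; children orphaned by the
removal become direct children of the implicit root, which keeps the DAG
connected so the path metrics stay defined. A class is deprecated when it
carries `owl:deprecated true`, an obo-style obsolescence annotation, or a
label starting with `OBSOLETE`; the predicate is configurable. Logical
consistency checking with a DL reasoner is out of scope — the reader exposes
the structural graph only, and a reasoner pre-filter can be applied upstream
before files reach the package.

## The synthetic generator

`generate_ontology()` emulates the structural features the metrics measure:
a levelled is-a DAG with a guaranteed construction depth (spine of one class
per level), a controllable fraction of multi-parent classes (second parents
always drawn from strictly shallower levels, so mutation can never create a
cycle), properties with controllable usage counts split between restriction
expressions and individual assertions, annotations, individuals and
deprecation flags. Every quantity is recorded as ground truth during
construction with independent bookkeeping, so tests can compare
`compute_metrics()` output against exact expected values rather than against
the implementation itself. `mutate_version()` applies an explicit edit plan
and returns the exact activity delta it induced, giving `diff_versions()` an
independent oracle. IRIs are minted deterministically and writers sort
entities, so a seed fixes the corpus byte-for-byte.

What the generator does *not* emulate: realistic lexical content (labels are
synthetic tokens), imports, reasoned hierarchies, and the heavy-tailed size
distributions of production ontologies. Passing tests therefore demonstrate
correctness of the computations on controlled structures, not calibration of
the static thresholds to any particular domain.

One published pipeline-sanity idea — a corpus degraded by "stripping usage"
each version should never gain mean change — is not monotone as stated:
usage counts enter the relationship-richness metric (higher better) and the
property-usage metrics (lower better) with opposite polarity, so removing
usages improves some scores while degrading others. The package's
directional-sanity test instead strips annotations and individuals, which
moves only two metrics (both higher-is-better) and leaves every other raw
value untouched, making "mean change ≤ 0 for every pair" a theorem rather
than a hope.

## Problem sizes and numerical notes

The test suite and examples run corpora of 3–6 versions with 10–50 classes,
where exhaustive oracles (full path enumeration, all contiguous partitions,
the exact signed-rank tail) are cheap; these sizes exercise every code path,
and the algorithms scale polynomially beyond them (the DP clustering is
O(k·d²) in the number of distinct values, path statistics are linear in
edges). Clustering cost comparisons use a 1e−12 slack to absorb floating
point; score boundaries are applied exactly as printed with no tolerance.
Dates and version order come from filenames unless the caller supplies
ordered paths, matching the usual release-directory layout.

## A small end-to-end run

```{r, eval = FALSE}
dir <- file.path(tempdir(), "corpus")
generate_corpus(dir, n_versions = 4,
                params = list(n_classes = 25, depth = 3, seed = 11),
                plans = mutation_plan(add_class = 2, edit_annotation = 2,
                                      seed = 5),
                seed = 11)
report <- oq_evaluate_corpus(dir, scale = "both")
report$change_stats$dynamic
plot_score_evolution(report$scores$dynamic)
plot_accumulative_profile(report$profiles$dynamic)
```
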