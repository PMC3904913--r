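---
title: "Measuring semantic particularity alongside similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring semantic particularity alongside similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(sempar)
```

## Why a second measure

Semantic similarity over Gene Ontology annotations is symmetric and
dominated by what two genes share. When one gene carries functions the
other lacks, similarity decreases only slowly, and it never says *which*
gene owns the surplus. `sempar` therefore reports every comparison as a
tuple (Sim, Par12, Par21): a symmetric similarity plus the particularity
of each annotation set relative to the other. High Sim with one high Par
flags a gene with genuine private functions despite overall resemblance —
a pattern invisible to similarity alone.

## The model

All computations happen inside one namespace of a directed acyclic
ontology whose child→parent edges are typed (`is_a`, `part_of`, and the
regulates family) and weighted. For a direct annotation set Sg, the
expanded set Sg\* adds every ancestor of every member (the true path
rule: an annotation implies all more general statements).

Given an informativeness function I(t) ≥ 0:

* MPT(Sg1, Sg2), the *most particular terms*, are the members of the
  direct set Sg1 with no descendant inside Sg1 and no membership in
  Sg2\*. Working on the direct set avoids counting a chain of related
  terms more than once; testing membership against the expansion treats
  ancestors of Sg2 terms as shared, not particular.
* The *particular informativeness*
  PI(Sg1, Sg2) = Σ over t in MPT of (I(t) − I(MICA(t, Sg2))), where the
  MICA is the most informative common ancestor-or-self of t within
  Sg2\*, taken as 0 when there is none. Subtracting the MICA removes the
  shared part of each private term's information, so common information
  is never double-counted.
* MCT(Sg1, Sg2), the *most informative common terms*, are the members of
  Sg1\* ∩ Sg2\* with no descendant in Sg1\* **and** none in Sg2\*. (The
  conjunctive reading is the one that makes the worked example below
  come out right: the deepest shared terms, nothing shallower.)
* Particularity: Par(Sg1, Sg2) = PI / (PI + Σ over MCT of I(t)). The
  denominator is the total informativeness of Sg1's most informative
  terms — private ones plus those shared with Sg2 — so Par lies in
  [0, 1].

Four properties characterise the measure and are enforced by randomized
property tests: it is non-symmetric; Par(S, S) = 0; Par(S, ∅) = 1 and
Par(∅, S) = 0 for nonempty S; and Par(S1, S2) is unchanged by enlarging
S2 with terms unrelated to S1. Comparing two empty sets is an error, and
Par(∅, S) = 0 is a convention (the ratio is 0/0 there), both documented
on `particularity()`.

On the property Par(S1, S2) = Par(S1, S2 ∪ S3): stated with the bare
precondition S3 ∩ S1 = ∅ it is false — an S3 member that is a descendant
of an S1 member enters S2\* and evicts that member from the MPT. The
package tests the sound version: S3 drawn from a subtree whose expansion
meets S1's expansion only at the root (which is in every expansion and
already in S2\* whenever S2 is nonempty, hence harmless).

## Informativeness backings

`sempar` deliberately separates the measure from the informativeness
that feeds it; three interchangeable backings implement the same
interface.

**Wang semantic value** (`sv_model()`). The contribution of an ancestor
t to a term a is the maximum, over descending paths from t to a, of the
product of edge factors; SV(a) sums the contributions of a and all its
ancestors, so SV(root) = 1 and SV grows with specificity. Factors
default to 0.8 (`is_a`), 0.6 (`part_of`) and 0.7 for all three regulates
variants — the regulates family is given one factor because reported
sensitivity of the overall value to it is on the order of ±0.01, and the
factors are configurable per relation anyway (`ontology_graph(weights=)`,
CLI `--weights`). With multiple parents each ancestor contributes once,
via its best path — the max-product dynamic programme — regardless of
how many paths reach it. SV is corpus-independent, which is what makes
cross-species comparison meaningful: term frequencies from different
species' corpora are not comparable, path products are.

**Information content** (`ic_model()`). IC(t) = −log p(t), where p(t) is
the fraction of annotated genes in the corpus whose expanded set
contains t. The denominator is the count of genes with at least one
annotation in the namespace, so p(root) = 1 and IC(root) = 0 exactly,
and IC is monotone along ancestry. Natural log by default (the usual
convention in GO IC tools; configurable via `base`); since Par is a
ratio of informativeness sums the base largely cancels, but mixing bases
across models would silently rescale PI against MCT, so it is fixed per
model. A term no gene covers has p = 0 and **no** IC: lookups error
rather than smooth, because an invented pseudo-frequency would leak into
Par invisibly.

**Explicit table** (`table_model()`). Lookup-backed, for frozen reruns
(`write_informativeness_tsv()` / `read_informativeness_tsv()`) and for
worked examples whose reference values are published numbers. Table
entries can be *sealed*: the worked-example fixture stores filler values
for intermediate terms the target computation must never consult, and a
sealed lookup raises an error instead of returning a number — a test
that silently used a filler would otherwise still pass.

Regulates edges participate both in Sg\* expansion and in the
contribution DP, consistently; restricting expansion to `is_a`/`part_of`
while weighting regulates in SV would make "shared" mean different
things in the numerator and denominator of Par.

With SV backing on multi-relation DAGs, I(t) < I(MICA) can occur (a term
reached only through low-factor edges can carry less semantic value than
a high-SV ancestor); such PI summands are clamped at zero with a
warning, keeping Par within [0, 1]. With IC backing the monotonicity of
IC makes clamping a no-op.

## Similarity

The Sim component is Wang's term similarity (shared contributions over
the two semantic values) or Lin's (2·IC(MICA)/(IC(a)+IC(b))), combined
across the pairwise term matrix by best-match average — the mean of the
two directional best-match means — or by `max` or `avg`. BMA is the
default because it is the common choice for gene-level aggregation; note
that `avg` does not satisfy sim(S, S) = 1, which is inherent to
averaging the full matrix, not a defect. Similarity of an empty set is
undefined and errors; the batch pipeline records such pairs as invalid
instead (reasons `one-unannotated`/`both-unannotated`), because in
cohort screens unannotated genes are data, not exceptions.

## The worked example

`exportin5_example()` encodes the molecular-function annotation sets of
the human, rat and fly Exportin-5 orthologs on a nine-term MF subgraph,
with published semantic values for the four terms the computation
touches (tRNA binding 4.201, binding 1.8, protein transporter activity
2.952, protein binding 2.44) plus I(root) = 1, which is not a guess: the
semantic value of a root is exactly its own contribution. The remaining
intermediate terms carry sealed fillers. The rat set is reconstructed
from the textual description of the example (no rat- or fly-specific
term; protein binding is the only human-specific term relative to rat),
so only quantities with published values are asserted: Par(hsa, dme) =
0.308, Par(hsa, rno) = 0.082, both reverse directions 0. The example's
published similarity values are *not* asserted — the combine strategy
behind them is unstated and the full term lists exist only as a figure.

```{r}
fx <- exportin5_example()
compare_sets(fx$graph, fx$model, fx$sets$hsa, fx$sets$dme,
             sim_method = "none")
```

## Batch pipeline

`pairwise_matrix()` computes the tuple for all unordered pairs of a gene
list in lexicographic order; `bin_particularity()` pools Par values into
20 half-open similarity bins of width 0.025 over [0.5, 0.999] (the last
bin closed; sim = 1 deliberately outside, as identical-profile pairs
would swamp the top bin); `classify_profiles()` partitions valid pairs
into four mutually exclusive profiles by thresholds θ_sim and θ_par
(default 0.5 each) with the valid-pair count as percentage baseline.
Both Par directions contribute to bin statistics by default
(`direction = "max"` keeps the larger per pair); the standard deviation
is the sample one unless `sd_type = "population"`. TSV output uses fixed
ordering and fixed `%.10g` formatting so reruns are byte-identical;
report-style outputs round to 3 decimals, with empty bins shown as "-".

## Synthetic data: what it does and does not establish

`random_dag()` grows a DAG term by term, each new term drawing 1–3
parents among earlier terms, so acyclicity and single-rootedness hold by
construction; relation types are drawn with defaults 0.7/0.2/0.1 for
is_a/part_of/regulates, roughly the proportions seen in GO's
biological-process graph. `random_corpus()` annotates each of the
default 20 genes with 1–5 uniformly drawn non-root terms — typical of a
modestly annotated namespace slice. Defaults were chosen once, on those
grounds, not tuned to test outcomes. Generation pins R's RNG
(Mersenne-Twister/Inversion/Rejection) locally, so fixtures are
reproducible across platforms and do not disturb the caller's RNG
stream.

These generators emulate topology and coverage, not GO's actual depth
distribution, term-name semantics, annotation bias towards well-studied
genes, or inter-species corpus heterogeneity. A green randomized suite
therefore establishes the formal properties and oracle equivalence of
the implementation — it does not certify conclusions about any real
corpus, which depend on annotation quality and completeness.

## Numerical choices and degenerate inputs

Ties among equally informative MICA candidates are harmless for values
(the max is unique); where a term must be named, the lexicographically
smallest id is chosen. Zero denominators: Par returns 1 against an empty
second set, else 0 with a warning when every relevant informativeness is
zero. Direct sets containing both a term and its ancestor are handled by
construction (the ancestor has a descendant in the set, so it can never
be a most particular term). Multi-namespace inputs error early; measures
are always per namespace.

## Known limitations

Only `is_a`, `part_of` and the regulates family are retained from OBO
input; other relationship types are dropped with a warning. OWL is not
parsed. Evidence codes are carried as metadata, never as weights.
Identifier mapping across databases, ortholog retrieval and any network
access are out of scope. The pairwise matrix is quadratic in genes and
the package is plain R; the per-graph memoisation keeps desk-scale
cohorts (hundreds of genes, thousands of terms) comfortable, but
database-scale screens of millions of pairs would want a compiled
backend.
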