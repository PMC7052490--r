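---
title: "Expression-weighted metabolic route search: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-weighted metabolic route search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaroutr)
```

## The problem

Metabolic reprogramming — the systematic shift in which pathways a tissue
actually uses — is a hallmark of cancer. Pathway databases tell us which
reactions are *possible*; transcriptomes tell us which enzymes are
*expressed* in a particular cohort. `metaroutr` combines the two: it builds
a directed graph whose nodes are compounds and whose edges are
enzyme-catalysed reactions weighted by cohort expression, then searches for
the routes between two compounds that the expression data supports best.

The central modelling assumption is that transcript abundance is a usable
proxy for enzymatic capacity. That is a deliberate simplification: it
ignores post-transcriptional regulation, enzyme kinetics and metabolite
concentrations. The ranking criteria are designed around it — a route is
only as good as its *least expressed* enzyme (the bottleneck), or as
*consistently expressed* as its enzymes are (stability).

## Graph construction

Four rules turn a reaction table and an expression cohort into a graph.

**Currency exclusion.** Compounds such as water, protons and the
ATP/ADP and NAD(P)H couples appear in a large fraction of all reactions.
Left in the graph they act as universal hubs and nearly every compound pair
becomes connected in two hops through biologically meaningless
"shortcuts", so they are excluded as intermediates. The default set is

```{r}
default_currency_set()
```

Currency status must be a query-time decision, not a constant: a search for
fatty-acid oxidation legitimately starts *at* coenzyme A, and an electron
transport chain query runs from NADH to NAD+. Two mechanisms support this:
the whole set can be replaced per run, and compounds passed to
`build_graph(..., retain = )` (typically the query's start and end) are kept
as nodes even if they are in the currency set — only their role as
*intermediates* is suppressed. Retained compounds are also the single
exception to the rule that isolated nodes are dropped: a compound the user
explicitly asked for stays addressable even with no surviving edge, so a
search against it reports "no route" rather than "unknown compound".

**Expression weighting.** Each (substrate, product) pair of each reaction
yields one candidate edge per catalysing gene, weighted by the selected
measure of that gene: the cohort `mean`, `median`, or `sv` (the standard
deviation of the expression vector). Modelling each isozyme as its own
candidate generalises reaction-level comparison: after collapse (below) the
best-expressed isozyme represents the step. Protein complexes requiring all
subunits are not modelled — each gene is treated as sufficient. Reactions
with no mapped gene (spontaneous reactions) yield no edges, since every
ranking criterion is defined on enzyme expression. Self-pairs (a compound on
both sides of one reaction) are skipped: a self-loop can never occur in a
simple path. Reversible reactions yield both directions; the flag defaults
to irreversible when absent from the input, because inventing edges is the
worse failure mode.

**Unexpressed-gene removal.** Genes with cohort mean expression strictly
below 1 are removed before construction (`filter_unexpressed()`), so noise
around zero cannot form edges. The comparison is strict: a mean of exactly
1 is kept. The threshold is in the units of the input matrix, which the
package treats as given — user and reference cohorts must share units
(counts, TPM, ...); no normalisation is applied.

**Parallel-edge collapse.** The final graph has at most one edge per
ordered compound pair: the candidate whose gene has the highest **mean**
expression wins, *regardless of the selected weight measure* — the collapse
comparison is always on the mean, while the surviving edge keeps the
selected measure as its weight. Ties are broken by the lexicographically
smallest (reaction id, gene) pair, and the collapsed edge list is sorted by
(source, target), which makes the graph — and everything downstream —
independent of input row order.

## Route search and ranking

A route is a **simple** directed path (no compound revisited) of at most
*N* reactions; *N* counts edges, and defaults to 8. Simplicity is what makes
"all possible pathways" finite: allowing cycles would diverge. Cyclic
pathways like the TCA cycle are queried by naming distinct start and end
compounds on the cycle (e.g. acetyl-CoA to NADH). Start and end must differ;
a zero-length route is not meaningful. Enumeration is exhaustive
depth-first search; no heuristic pruning is applied by default.

Scoring:

* **bottleneck** — `min` of edge weights, ranked descending. This is the
  max–min (widest path) objective: the route whose weakest enzyme is
  strongest.
* **stability** — standard deviation of edge weights, ranked ascending.
  A single-edge route scores 0.

The top *K* routes are returned (default 10). Ties are broken by fewer
reactions first (parsimony), then by the lexicographic order of the
compound chain, so rankings are fully deterministic and repeated runs are
byte-identical.

An optional branch-and-bound (`prune = TRUE`, bottleneck only) abandons a
DFS branch when its running minimum falls strictly below the current K-th
best completed bottleneck. The bound is admissible — any completed
extension of the branch would score below K routes already found — so its
output is provably identical to full enumeration, and the test suite
verifies that equivalence on every oracle graph. No analogous prefix bound
exists for stability (the standard deviation of a prefix does not bound
that of its extensions), so pruning is rejected for that criterion.

## Numerical conventions

* `sv` uses the sample standard deviation (denominator *n* − 1) and is
  defined as 0 for a single sample or a constant vector, keeping every
  gene total. The same convention scores route stability.
* The median of an even-length vector is the mean of the two middle order
  statistics.
* Fold-change classes use exclusive thresholds: `up` strictly above 2,
  `down` strictly below 0.5, `neutral` otherwise (a fold change of exactly
  2 is neutral). With the default pseudocount of 0, a zero reference mean
  or a gene missing from the reference yields class `undefined` — no
  regulation call is fabricated; a pseudocount is strictly opt-in. Genes in
  the reference but absent from the user cohort are simply not annotated.
* Scores are serialized with six significant digits; expression values with
  six decimals, which makes write→read→write cycles byte-identical.
* Gene symbols are uppercased on ingest; compound names are matched exactly
  and case-sensitively, since compound nomenclature is chemically
  meaningful.

## The synthetic-data generator

Because the reference reaction database and tumor expression cohorts are
licensed resources, the package ships a generator
(`fixture_spec()`, `generate_reaction_table()`, `generate_expression()`,
`plant_pathway()`) that emulates their statistical shape:

* a random directed reaction network (default 30 compounds, 40 reactions,
  1–3 isozymes per reaction, 20% reversible) in which 3 currency
  metabolites appear with elevated frequency, one reaction pair shares a
  compound pair (exercising collapse) and at least one reaction is
  reversible;
* log-normal expression (location 1, scale 1, 10 samples) — positive and
  right-skewed like RNA-seq quantifications — with 10% of genes rescaled
  below the expression threshold so filtering is always exercised;
* optionally a *planted route*: fresh reactions along a chosen compound
  chain, catalysed by fresh genes whose expression is constant at a `floor`
  that must strictly exceed the maximum background mean. The check is
  enforced, not assumed: planting refuses a floor at or below the
  background maximum. By construction the planted route's bottleneck
  (= `floor`) exceeds every competitor's (≤ background maximum), so a
  correct search must return it at rank 1 — this is the package's
  recovery benchmark, and its stability score is exactly 0.

What the generator does **not** emulate: scale-free degree structure,
correlated expression between functionally related genes,
compartmentalisation, stoichiometry, or cancer-type-specific signal.
Passing the recovery and oracle checks therefore demonstrates algorithmic
correctness, not biological validity on real cohorts.

## Verification design

Every algorithmic component is checked against an independent oracle rather
than against itself: enumeration against a literal permutation-enumeration
brute force on tiny graphs and against igraph's exhaustive simple-path
search across 100 seeded random graphs (up to 12 nodes, 30 edges, route
caps of 3–6 — sizes at which exhaustive verification is exact and fast);
ranking against a full sort; graph construction against a quadruple-loop
re-derivation and a hand-derived six-reaction audit covering every rule;
statistics against their definitional formulas on 500 random inputs. The
same checks, recomputed from scratch at the same problem sizes, are what
`scripts/acceptance.R` reports.

## Limitations

Stoichiometric coefficients, atom mapping, flux-balance constraints,
thermodynamic feasibility and kinetic (K_cat) weighting are out of scope:
a top-ranked route is a hypothesis consistent with expression, not a proven
flux. Compound synonym resolution is not attempted — names must match the
reaction table exactly. The fold-change annotation compares a single user
value per gene against the reference mean; it is a screening heuristic, not
a differential-expression test.
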